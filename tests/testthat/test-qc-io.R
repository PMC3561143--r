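makePedMapFiles <- function(pedLines, mapLines) {
  pedPath <- tempfile(fileext = ".ped")
  mapPath <- tempfile(fileext = ".map")
  writeLines(pedLines, pedPath)
  writeLines(mapLines, mapPath)
  list(ped = pedPath, map = mapPath)
}

test_that("PED/MAP reading assigns codes and round-trips bit-identically", {
  f <- makePedMapFiles(
    c("FAM1 ID1 0 0 1 2 A A A G 0 0",
      "FAM1 ID2 0 0 2 1 A C G G T T"),
    c("1 rs1 0 1000",
      "1 rs2 1.5 2000",
      "1 rs3 3 3500"))
  g <- readPedMap(f$ped, f$map)
  geno <- genoCodes(g)
  map <- snpInfo(g)
  expect_equal(dim(geno), c(3, 2))
  expect_equal(map$allele1, c("A", "A", "T"))
  expect_equal(unname(geno[, "ID1"]), c(0L, 1L, NA))  # "A G" het, "0 0" miss
  expect_equal(unname(geno[, "ID2"]), c(1L, 2L, 0L))
  expect_equal(map$cM, c(0, 1.5, 3))

  out <- makePedMapFiles(character(0), character(0))
  writePedMap(g, out$ped, out$map)
  expect_identical(readLines(out$ped), readLines(f$ped))
  expect_identical(readLines(out$map), readLines(f$map))
})

test_that("malformed PED/MAP input is rejected", {
  f <- makePedMapFiles(
    c("F I1 0 0 1 2 A A", "F I2 0 0 1 2 A G", "F I3 0 0 1 2 T T"),
    "1 rs1 0 1000")
  expect_error(readPedMap(f$ped, f$map), "more than two alleles")

  f2 <- makePedMapFiles("F I1 0 0 1 2 A A",
                        c("1 rs1 0 1000", "1 rs2 1 2000"))
  expect_error(readPedMap(f2$ped, f2$map), "does not match")

  f3 <- makePedMapFiles("F I1 0 0 1 2 A A G G",
                        c("1 rs1 0 5000", "1 rs2 1 2000"))
  expect_error(readPedMap(f3$ped, f3$map), "strictly increasing")
})

test_that("round trip is lossless for random genotype matrices", {
  set.seed(11)
  for (rep in 1:5) {
    inst <- randomGenoInstance(nCase = 6, nSnp = 40, nChr = 3,
                               missRate = 0.1)
    map <- uniformMap(40, nChr = 3)
    colnames(inst$geno) <- paste0("IND", 1:6)
    x <- SnpGenotypes(inst$geno, map)
    f <- makePedMapFiles(character(0), character(0))
    writePedMap(x, f$ped, f$map)
    y <- readPedMap(f$ped, f$map)
    expect_equal(unname(genoCodes(y)), unname(genoCodes(x)))
    expect_equal(snpInfo(y)$bp, snpInfo(x)$bp)
    expect_equal(snpInfo(y)$cM, snpInfo(x)$cM)
  }
})

test_that("exact HWE test matches the enumeration oracle and known limits", {
  expect_equal(hweTest(25, 50, 25), 1, tolerance = 1e-9)   # exact proportions
  expect_lt(hweTest(50, 0, 50), 1e-4)                      # het deficit
  expect_equal(hweTest(10, 0, 0), 1)                       # monomorphic

  set.seed(99)
  for (rep in 1:40) {
    n <- sample(5:200, 1)
    n11 <- sample(0:n, 1)
    n12 <- sample(0:(n - n11), 1)
    n22 <- n - n11 - n12
    if (n11 + n12 + n22 == 0) next
    expect_equal(hweTest(n11, n12, n22),
                 hweEnumOracle(n11, n12, n22), tolerance = 1e-9,
                 label = paste("counts", n11, n12, n22))
  }
})

buildQcFixture <- function() {
  # 5 SNPs x (4 cases + 100 controls), built so exactly 2 SNPs fail exactly
  # one filter each: snp2 misses > 5% overall, snp4 has control MAF < 1%
  set.seed(7)
  nCa <- 4; nCo <- 100
  geno <- matrix(1L, 5, nCa + nCo)
  # snp1, snp3, snp5: clean HWE-ish genotypes, common alleles
  for (s in c(1, 3, 5)) {
    geno[s, ] <- stats::rbinom(nCa + nCo, 2, 0.4)
  }
  # snp2: 6 of the 100 controls missing (6/104 combined > 5%)
  geno[2, ] <- stats::rbinom(nCa + nCo, 2, 0.5)
  geno[2, nCa + (1:6)] <- NA
  # snp4: control MAF 0.5% (1 het among 100 controls)
  geno[4, ] <- 0L
  geno[4, nCa + 1] <- 1L
  colnames(geno) <- c(paste0("CASE", 1:nCa), paste0("CTRL", 1:nCo))
  map <- uniformMap(5)
  SnpGenotypes(geno, map)
}

test_that("QC filters remove the designed failures and tally correctly", {
  x <- buildQcFixture()
  cases <- paste0("CASE", 1:4)
  controls <- paste0("CTRL", 1:100)
  res <- filterSnps(x, cases, controls)
  rep <- res$report
  expect_false(rep$pass[2])
  expect_match(rep$reasons[2], "missRate")
  expect_false(rep$pass[4])
  expect_match(rep$reasons[4], "maf")
  expect_equal(sum(rep$pass), 3)
  expect_equal(nrow(genoCodes(res$genotypes)), 3)
  tot <- attr(rep, "totals")
  expect_equal(unname(tot["input"]), 5)
  expect_equal(unname(tot["retained"] + tot["removedAny"]), 5)

  # boundary behaviour of the MAF rule: 0.9% removed, 1.1% kept
  g2 <- matrix(0L, 2, 500)
  g2[1, 1:9] <- 1L            # MAF 0.009
  g2[2, 1:11] <- 1L           # MAF 0.011
  colnames(g2) <- paste0("S", 1:500)
  y <- SnpGenotypes(g2, uniformMap(2))
  res2 <- filterSnps(y, caseIds = character(0),
                     controlIds = colnames(g2),
                     thresholds = list(hweP = 0))   # isolate the MAF rule
  expect_false(res2$report$pass[1])
  expect_true(res2$report$pass[2])
})

test_that("QC filters are order-independent", {
  # filters are computed on the unfiltered input, so applying any single
  # filter then the rest must retain the same set as all at once
  x <- buildQcFixture()
  cases <- paste0("CASE", 1:4)
  controls <- paste0("CTRL", 1:100)
  all <- filterSnps(x, cases, controls)$report
  single <- list(
    filterSnps(x, cases, controls,
               thresholds = list(maf = 0, hweP = 0, diffMissP = 0))$report,
    filterSnps(x, cases, controls,
               thresholds = list(missRate = 1, hweP = 0,
                                 diffMissP = 0))$report)
  joint <- single[[1]]$pass & single[[2]]$pass
  expect_equal(all$pass, joint)
})

test_that("empty control set is rejected when MAF/HWE filters are active", {
  x <- buildQcFixture()
  expect_error(filterSnps(x, paste0("CASE", 1:4), character(0)),
               "control set")
})
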