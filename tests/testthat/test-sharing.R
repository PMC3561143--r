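test_that("pair sharing rule: only opposite homozygotes cannot share", {
  expect_false(pairShares(0L, 2L))
  expect_false(pairShares(2L, 0L))
  expect_true(pairShares(NA, 0L))     # missing treated as heterozygote
  expect_true(pairShares(NA, 2L))
  # exhaustive code table (0, 1, 2, NA): exactly 2 of 16 cells are FALSE
  codes <- c(0L, 1L, 2L, NA)
  tab <- outer(seq_along(codes), seq_along(codes),
               Vectorize(function(i, j) pairShares(codes[i], codes[j])))
  expect_equal(sum(!tab), 2)
  expect_equal(sum(tab), 14)
})

test_that("locus sharing counts follow S = N - min(N11, N22) with bounds", {
  # N = 5: one hom-1, one hom-2, three het
  expect_equal(locusSharingCount(matrix(c(0L, 2L, 1L, 1L, 1L), 1)), 4L)
  # all five heterozygous
  expect_equal(locusSharingCount(matrix(rep(1L, 5), 1)), 5L)
  # bound check over random codes: ceiling(N/2) <= S <= N
  set.seed(31)
  for (N in c(5, 10)) {
    geno <- matrix(sample(c(0:2, NA), 200 * N, replace = TRUE), 200, N)
    S <- locusSharingCount(geno)
    expect_true(all(S >= ceiling(N / 2)))
    expect_true(all(S <= N))
    expect_equal(as.numeric(S), sharingCountOracle(geno))
  }
})

test_that("run lengths mark each locus with its maximal block", {
  expect_equal(runLengths(c(TRUE, TRUE, FALSE, TRUE)), c(2L, 2L, 0L, 1L))
  expect_equal(runLengths(rep(FALSE, 4)), rep(0L, 4))
  expect_equal(runLengths(rep(TRUE, 3)), rep(3L, 3))
  # runs never cross chromosome boundaries
  expect_equal(runLengths(rep(TRUE, 4), chr = c(1, 1, 2, 2)),
               rep(2L, 4))
  set.seed(8)
  for (rep in 1:30) {
    v <- runif(sample(5:50, 1)) < 0.6
    expect_equal(runLengths(v), runLengthOracle(v))
  }
})

test_that("pairwise run lengths behave on constructed cases", {
  # identical homozygous genotypes: maximal run everywhere
  g <- matrix(0L, 100, 2)
  r <- pairwiseRunLengths(g, chr = rep("c1", 100))
  expect_true(all(r == 100L))
  # opposite homozygotes at one middle SNP split the run
  g2 <- matrix(1L, 9, 2)
  g2[5, ] <- c(0L, 2L)
  r2 <- pairwiseRunLengths(g2, chr = rep("c1", 9))
  expect_equal(as.integer(r2), c(rep(4L, 4), 0L, rep(4L, 4)))
})

test_that("pSGS is the d-weighted mean of pairwise run lengths", {
  runs <- matrix(c(10, 20, 30), 1)
  expect_equal(psgsStatistic(runs, c(2, 4, 6)), (20 + 80 + 180) / 12)
  # equal weights reduce to the plain mean
  expect_equal(psgsStatistic(runs, c(1, 1, 1)), 20)
  # scale invariance of the weights
  expect_equal(psgsStatistic(runs, 7 * c(2, 4, 6)),
               psgsStatistic(runs, c(2, 4, 6)))
  expect_error(psgsStatistic(runs, c(1, 2)), "weights")
})

test_that("SGS runs break where any opposite-homozygote pair occurs", {
  g <- matrix(1L, 50, 4)
  expect_equal(as.integer(sgsStatistic(g, chr = rep("c1", 50))),
               rep(50L, 50))
  g[20, 1:2] <- c(0L, 2L)
  s <- sgsStatistic(g, chr = rep("c1", 50))
  expect_equal(s[20], 0L)
  expect_equal(s[19], 19L)
  expect_equal(s[21], 30L)
})

test_that("sharing statistics match brute-force oracles on random instances", {
  set.seed(77)
  for (rep in 1:25) {
    N <- sample(3:8, 1)
    L <- sample(40:200, 1)
    inst <- randomGenoInstance(N, L, nChr = sample(1:3, 1))
    d <- sample(2:11, choose(N, 2), replace = TRUE)
    oR <- pairRunsOracle(inst$geno, inst$chr)
    runs <- pairwiseRunLengths(inst$geno, inst$chr)
    expect_equal(unname(runs[, ]), unname(oR))
    expect_equal(psgsStatistic(runs, d),
                 as.numeric(oR %*% d) / sum(d))
    expect_equal(as.numeric(twoPedigreeStatistic(inst$geno, inst$chr)),
                 rowMeans(oR))
    S <- locusSharingCount(inst$geno)
    expect_equal(as.numeric(S), sharingCountOracle(inst$geno))
    allShare <- S == N
    oracleSgs <- unlist(lapply(
      split(seq_len(L), factor(inst$chr, levels = unique(inst$chr))),
      function(ix) runLengthOracle(allShare[ix])), use.names = FALSE)
    expect_equal(as.integer(sgsStatistic(inst$geno, inst$chr)), oracleSgs)
  }
})

test_that("statistics are invariant to case order and allele relabeling", {
  set.seed(55)
  inst <- randomGenoInstance(5, 120, nChr = 2)
  d <- c(2, 4, 4, 6, 4, 6, 6, 8, 8, 2)
  runs <- pairwiseRunLengths(inst$geno, inst$chr)
  psgs <- psgsStatistic(runs, d)
  sgs <- sgsStatistic(inst$geno, inst$chr)

  # relabel alleles 1 <-> 2 at a random subset of SNPs
  flip <- sample(c(TRUE, FALSE), 120, replace = TRUE)
  g2 <- inst$geno
  g2[flip, ] <- 2L - g2[flip, ]
  expect_equal(sgsStatistic(g2, inst$chr), sgs)
  expect_equal(locusSharingCount(g2), locusSharingCount(inst$geno))

  # permute cases (permuting the pair weights accordingly)
  perm <- sample(5)
  g3 <- inst$geno[, perm]
  pr <- utils::combn(5, 2)
  key <- function(a, b) paste(min(a, b), max(a, b))
  names(d) <- apply(pr, 2, function(x) key(x[1], x[2]))
  d3 <- apply(pr, 2, function(x) d[[key(perm[x[1]], perm[x[2]])]])
  expect_equal(psgsStatistic(pairwiseRunLengths(g3, inst$chr), d3), psgs)
})

test_that("R_i(t) is non-increasing in t and saturates when all pairs share", {
  set.seed(66)
  inst <- randomGenoInstance(6, 100, nChr = 1)
  tracks <- sapply(3:6, function(t)
    as.integer(sgsStatistic(inst$geno, inst$chr, t = t)))
  for (i in seq_len(nrow(tracks)))
    expect_true(all(diff(tracks[i, ]) <= 0))

  # all heterozygotes: every pair shares everywhere, psgs = sgs = L
  g <- matrix(1L, 40, 5)
  chr <- rep("c1", 40)
  runs <- pairwiseRunLengths(g, chr)
  expect_true(all(psgsStatistic(runs, rep(2, 10)) == 40))
  expect_true(all(sgsStatistic(g, chr) == 40L))
})

test_that("two-pedigree statistic reduces and counts pairs correctly", {
  # one case per pedigree: the statistic is the single pairwise run length
  g <- matrix(c(0L, 0L, 1L, 2L, 0L, 0L), 3, 2)
  chr <- rep("c1", 3)
  expect_equal(as.numeric(twoPedigreeStatistic(g, chr)),
               as.numeric(pairwiseRunLengths(g, chr)[, 1]))
  # 5 + 10 pooled cases average over choose(15, 2) = 105 pairs
  inst <- randomGenoInstance(15, 30, nChr = 1)
  runs <- pairwiseRunLengths(inst$geno, inst$chr)
  expect_equal(ncol(runs), 105)
})

test_that("region sharing summaries tally mean and range", {
  S <- c(4L, 4L, 4L, 4L)
  expect_equal(regionSharingSummary(S, 1:4),
               c(mean = 4, min = 4, max = 4))
  expect_equal(regionSharingSummary(c(3L, 5L, 5L, 5L), 1:4),
               c(mean = 4.5, min = 3, max = 5))
  set.seed(12)
  S2 <- sample(3:10, 50, replace = TRUE)
  loci <- sample(50, 12)
  expect_equal(regionSharingSummary(S2, loci),
               c(mean = mean(S2[loci]), min = min(S2[loci]),
                 max = max(S2[loci])))
  expect_error(regionSharingSummary(S2, integer(0)), "empty")
})

test_that("sharingProfile assembles consistent tracks", {
  ped <- pedigreeTemplate("cousins5")
  cfg <- syntheticConfig(nChrom = 2, snpsPerChrom = 40, seed = 19)
  tm <- generateTruthModel(cfg)
  drop <- dropGenome(ped, tm$model, tm$map, seed = 7)
  prof <- sharingProfile(drop, ped)
  expect_equal(length(psgsTrack(prof)), 80)
  expect_equal(psgsTrack(prof),
               psgsStatistic(pairRuns(prof), prof@pairs$d))
  expect_equal(as.integer(sgsTrack(prof)),
               as.integer(sgsStatistic(caseGenotypes(drop)[, caseIds(ped)],
                                       tm$map$chr)))
})
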