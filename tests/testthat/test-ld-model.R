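# Simulate a control panel directly from explicit two-locus haplotype
# frequencies (independent of the package's own samplers).
panelFromHapFreqs <- function(hapFreq, n, seed) {
  # hapFreq: named vector over c("11", "12", "21", "22")
  set.seed(seed)
  haps <- sample(names(hapFreq), 2 * n, replace = TRUE, prob = hapFreq)
  a1 <- as.integer(substr(haps, 1, 1))
  a2 <- as.integer(substr(haps, 2, 2))
  geno <- rbind((a1[1:n] - 1L) + (a1[n + 1:n] - 1L),
                (a2[1:n] - 1L) + (a2[n + 1:n] - 1L))
  colnames(geno) <- paste0("S", 1:n)
  SnpGenotypes(geno, uniformMap(2))
}

test_that("two SNPs in complete LD give a near-deterministic transition", {
  panel <- panelFromHapFreqs(c("11" = 0.6, "12" = 0, "21" = 0, "22" = 0.4),
                             n = 500, seed = 1)
  fit <- fitMarkovLD(panel)
  tr <- fit@chrom[[1]]$trans[[1]]
  expect_gte(tr[1, 1], 0.99)   # P(next = 1 | prev = 1)
  expect_gte(tr[2, 2], 0.99)
})

test_that("linkage equilibrium gives transitions equal to the marginal", {
  q <- 0.3  # allele-1 frequency at SNP 2
  hf <- c("11" = 0.5 * q, "12" = 0.5 * (1 - q),
          "21" = 0.5 * q, "22" = 0.5 * (1 - q))
  panel <- panelFromHapFreqs(hf, n = 2000, seed = 2)
  fit <- fitMarkovLD(panel)
  tr <- fit@chrom[[1]]$trans[[1]]
  expect_lt(abs(tr[1, 1] - tr[2, 1]), 0.03)
  expect_lt(abs(tr[1, 1] - q), 0.03)
})

test_that("fitting recovers a known order-1 model from a large panel", {
  cfg <- syntheticConfig(nChrom = 1, snpsPerChrom = 100, seed = 5)
  truth <- generateTruthModel(cfg)
  panel <- generateControlPanel(truth$model, truth$map, 2000, seed = 9)
  fit <- fitMarkovLD(panel)
  worst <- max(vapply(1:99, function(t)
    max(abs(fit@chrom[[1]]$trans[[t]] - truth$model@chrom[[1]]$trans[[t]])),
    numeric(1)))
  expect_lt(worst, 0.05)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(3)
  pairs <- pedSGS:::.patternPairs(2L)
  for (rep in 1:10) {
    g1 <- sample(0:2, 80, replace = TRUE)
    g2 <- sample(0:2, 80, replace = TRUE)
    code <- g1 + 3L * g2
    fit <- pedSGS:::.emWindow(table(code), 2L, pairs)
    ll <- fit$logLikTrace
    if (length(ll) > 1)
      expect_true(all(diff(ll) >= -1e-9))
  }
})

test_that("haplotype sampling is reproducible and honours the model", {
  cfg <- syntheticConfig(nChrom = 1, snpsPerChrom = 60, seed = 4)
  truth <- generateTruthModel(cfg)

  h1 <- sampleHaplotype(truth$model, "chr1", n = 5, seed = 77)
  h2 <- sampleHaplotype(truth$model, "chr1", n = 5, seed = 77)
  expect_identical(h1, h2)

  # deterministic chain supports exactly one haplotype
  det <- truth$model
  det@chrom[[1]]$init <- c(1, 0)
  for (t in seq_along(det@chrom[[1]]$trans))
    det@chrom[[1]]$trans[[t]] <- rbind(c(1, 0), c(1, 0))
  hd <- sampleHaplotype(det, "chr1", n = 3, seed = 1)
  expect_true(all(hd == 1L))

  # marginal allele frequencies of many draws match the chain's marginals
  draws <- sampleHaplotype(truth$model, "chr1", n = 10000, seed = 123)
  emp <- rowMeans(draws == 1L)
  marg <- numeric(60)
  marg[1] <- truth$model@chrom[[1]]$init[1]
  for (t in 1:59) {
    tr <- truth$model@chrom[[1]]$trans[[t]]
    marg[t + 1] <- marg[t] * tr[1, 1] + (1 - marg[t]) * tr[2, 1]
  }
  se <- sqrt(marg * (1 - marg) / 10000)
  expect_true(all(abs(emp - marg) < 3.5 * se + 1e-6))
})

test_that("sampled adjacent-pair haplotype frequencies match the model", {
  cfg <- syntheticConfig(nChrom = 1, snpsPerChrom = 20, ldStrength = 0.6,
                         seed = 6)
  truth <- generateTruthModel(cfg)
  draws <- sampleHaplotype(truth$model, "chr1", n = 10000, seed = 55)
  marg <- numeric(20)
  marg[1] <- truth$model@chrom[[1]]$init[1]
  for (t in 1:19) {
    tr <- truth$model@chrom[[1]]$trans[[t]]
    marg[t + 1] <- marg[t] * tr[1, 1] + (1 - marg[t]) * tr[2, 1]
  }
  for (t in c(1, 7, 19)) {
    tr <- truth$model@chrom[[1]]$trans[[t]]
    for (a in 1:2) for (b in 1:2) {
      expected <- (if (a == 1) marg[t] else 1 - marg[t]) * tr[a, b]
      emp <- mean(draws[t, ] == a & draws[t + 1, ] == b)
      expect_lt(abs(emp - expected),
                3.5 * sqrt(expected * (1 - expected) / 10000) + 2e-3)
    }
  }
})

test_that("refitting on data sampled from a fitted model is self-consistent", {
  cfg <- syntheticConfig(nChrom = 1, snpsPerChrom = 40, seed = 8)
  truth <- generateTruthModel(cfg)
  panel <- generateControlPanel(truth$model, truth$map, 2000, seed = 21)
  fit1 <- fitMarkovLD(panel)
  panel2 <- generateControlPanel(fit1, snpInfo(panel), 2000, seed = 22)
  fit2 <- fitMarkovLD(panel2)
  drift <- max(vapply(seq_along(fit1@chrom[[1]]$trans), function(t)
    max(abs(fit1@chrom[[1]]$trans[[t]] - fit2@chrom[[1]]$trans[[t]])),
    numeric(1)))
  expect_lt(drift, 0.05)
})

test_that("LD model serialization round-trips", {
  cfg <- syntheticConfig(nChrom = 2, snpsPerChrom = 15, seed = 10)
  truth <- generateTruthModel(cfg)
  panel <- generateControlPanel(truth$model, truth$map, 100, seed = 31)
  fit <- fitMarkovLD(panel)
  f <- tempfile(fileext = ".json")
  writeLDModel(fit, f)
  back <- readLDModel(f)
  expect_equal(back@order, fit@order)
  expect_equal(names(back@chrom), names(fit@chrom))
  for (chr in names(fit@chrom)) {
    expect_equal(back@chrom[[chr]]$init, fit@chrom[[chr]]$init,
                 tolerance = 1e-12)
    for (t in seq_along(fit@chrom[[chr]]$trans))
      expect_equal(back@chrom[[chr]]$trans[[t]],
                   fit@chrom[[chr]]$trans[[t]], tolerance = 1e-12)
  }
})
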