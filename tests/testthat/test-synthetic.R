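test_that("LD-strength knob spans equilibrium to near-deterministic", {
  cfg0 <- syntheticConfig(nChrom = 1, snpsPerChrom = 30, ldStrength = 0,
                          seed = 3)
  tm0 <- generateTruthModel(cfg0)
  for (t in 1:29) {
    tr <- tm0$model@chrom[[1]]$trans[[t]]
    expect_equal(tr[1, ], tr[2, ], tolerance = 1e-12)  # equals the marginal
  }
  cfg1 <- syntheticConfig(nChrom = 1, snpsPerChrom = 30, ldStrength = 1,
                          seed = 3)
  tm1 <- generateTruthModel(cfg1)
  for (t in 1:29) {
    tr <- tm1$model@chrom[[1]]$trans[[t]]
    expect_gte(tr[1, 1], 0.99)
    expect_gte(tr[2, 2], 0.99)
  }
})

test_that("the generator is reproducible from its master seed", {
  cfg <- syntheticConfig(nChrom = 2, snpsPerChrom = 25, seed = 77,
                         carrierFraction = 0.6)
  a <- generateTruthModel(cfg)
  b <- generateTruthModel(cfg)
  expect_identical(a, b)
  pa <- generateControlPanel(a$model, a$map, 20, seed = 5)
  pb <- generateControlPanel(b$model, b$map, 20, seed = 5)
  expect_identical(genoCodes(pa), genoCodes(pb))
  ga <- generateCaseGenotypes(NULL, a$model, a$map, cfg)
  gb <- generateCaseGenotypes(NULL, b$model, b$map, cfg)
  expect_identical(genoCodes(ga$genotypes), genoCodes(gb$genotypes))
  expect_identical(ga$truth, gb$truth)
})

test_that("control panels support LD-model recovery at study sizes", {
  cfg <- syntheticConfig(nChrom = 1, snpsPerChrom = 100, seed = 5)
  truth <- generateTruthModel(cfg)
  meanAbsErr <- function(n, seed) {
    panel <- generateControlPanel(truth$model, truth$map, n, seed = seed)
    fit <- fitMarkovLD(panel)
    mean(vapply(1:99, function(t)
      mean(abs(fit@chrom[[1]]$trans[[t]] -
               truth$model@chrom[[1]]$trans[[t]])), numeric(1)))
  }
  # recovery improves with panel size; 224 matches the study's control count
  expect_lt(meanAbsErr(224, 9), 0.08)
  expect_lt(meanAbsErr(2000, 9), 0.03)
  # degenerate panel still runs
  tiny <- generateControlPanel(truth$model, truth$map, 2, seed = 1)
  expect_s4_class(fitMarkovLD(tiny), "HaplotypeLDModel")
})

test_that("full carrier load forces IBS sharing of all cases at the risk locus", {
  cfg <- syntheticConfig(pedigree = "cousins5", nChrom = 1,
                         snpsPerChrom = 60, carrierFraction = 1,
                         missingRate = 0, errorRate = 0, seed = 21)
  tm <- generateTruthModel(cfg)
  g <- generateCaseGenotypes(NULL, tm$model, tm$map, cfg)
  expect_equal(length(g$truth$carriers), 5)
  S <- locusSharingCount(genoCodes(g$genotypes))
  expect_equal(S[g$truth$riskIndex], 5L)
  geno <- genoCodes(g$genotypes)[g$truth$riskIndex, ]
  for (a in 1:4) for (b in (a + 1):5)
    expect_true(pairShares(geno[a], geno[b]))
})

test_that("declared carriers exactly match the IBD labels at the risk locus", {
  ped <- pedigreeTemplate("cousins5")
  for (seed in c(1, 2, 3)) {
    cfg <- syntheticConfig(pedigree = "cousins5", nChrom = 1,
                           snpsPerChrom = 50, carrierFraction = 0.6,
                           missingRate = 0.05, errorRate = 0.01, seed = seed)
    tm <- generateTruthModel(cfg)
    g <- generateCaseGenotypes(ped, tm$model, tm$map, cfg)
    lab <- ibdLabels(g$drop)
    hasGam <- lab$lab1[g$truth$riskIndexLocal, ] == g$truth$founderGamete |
              lab$lab2[g$truth$riskIndexLocal, ] == g$truth$founderGamete
    expect_equal(sort(caseIds(ped)[hasGam]), g$truth$carriers)
    expect_true(all(g$truth$carriers %in% caseIds(ped)))
  }
})

test_that("zero carrier fraction reduces to a pure gene-dropping null", {
  ped <- pedigreeTemplate("cousins5")
  cfg <- syntheticConfig(pedigree = "cousins5", nChrom = 1,
                         snpsPerChrom = 100, carrierFraction = 0,
                         missingRate = 0, errorRate = 0, seed = 31)
  tm <- generateTruthModel(cfg)
  mid <- 50L
  fromGenerator <- vapply(1:200, function(r) {
    c2 <- cfg; c2$seed <- r
    g <- generateCaseGenotypes(ped, tm$model, tm$map, c2)
    psgsStatistic(pairwiseRunLengths(genoCodes(g$genotypes), tm$map$chr),
                  pairTable(ped)$d)[mid]
  }, numeric(1))
  fromNull <- vapply(1:200, function(r) {
    d <- dropGenome(ped, tm$model, tm$map, seed = 5000 + r)
    psgsStatistic(pairwiseRunLengths(caseGenotypes(d), tm$map$chr),
                  pairTable(ped)$d)[mid]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(fromGenerator, fromNull))
  expect_gt(ks$p.value, 0.01)
})

test_that("missingness and genotype error are injected at the configured rates", {
  cfg <- syntheticConfig(pedigree = "cousins5", nChrom = 4,
                         snpsPerChrom = 250, carrierFraction = 0,
                         missingRate = 0.03, errorRate = 0, seed = 41)
  tm <- generateTruthModel(cfg)
  g <- generateCaseGenotypes(NULL, tm$model, tm$map, cfg)
  obsMiss <- mean(is.na(genoCodes(g$genotypes)))
  expect_gt(obsMiss, 0.02)
  expect_lt(obsMiss, 0.04)

  cfgE <- syntheticConfig(pedigree = "cousins5", nChrom = 4,
                          snpsPerChrom = 250, carrierFraction = 0,
                          missingRate = 0, errorRate = 0.05, seed = 42)
  tmE <- generateTruthModel(cfgE)
  gE <- generateCaseGenotypes(NULL, tmE$model, tmE$map, cfgE)
  flips <- mean(genoCodes(gE$genotypes) != caseGenotypes(gE$drop))
  expect_gt(flips, 0.03)
  expect_lt(flips, 0.07)
})
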