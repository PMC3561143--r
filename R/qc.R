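## SNP quality control: exact Hardy-Weinberg test, per-SNP missingness,
## minor allele frequency, differential case/control missingness.

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.  A chi-square
#' (1 df) alternative is available for large samples.  Monomorphic input
#' returns p = 1.
#'
#' @param n11,n12,n22 genotype counts (hom allele-1, het, hom allele-2).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-value in (0, 1].
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions: p = 1
#' hweTest(50, 0, 50)    # total heterozygote deficit: p << 1e-4
#' @export
hweTest <- function(n11, n12, n22, method = c("exact", "chisq")) {
  method <- match.arg(method)
  n11 <- as.integer(n11); n12 <- as.integer(n12); n22 <- as.integer(n22)
  if (min(n11, n12, n22) < 0L || n11 + n12 + n22 < 1L)
    stop("genotype counts must be non-negative with a positive total")
  n <- n11 + n12 + n22
  nA <- 2L * n11 + n12          # minor or major: symmetry handled below
  nB <- 2L * n22 + n12
  if (nA == 0L || nB == 0L) return(1)
  if (method == "chisq") {
    p <- nA / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((c(n11, n12, n22) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  nR <- min(nA, nB)             # rarer allele count
  hets <- seq(nR %% 2L, nR, by = 2L)   # feasible heterozygote counts
  ## log P(n12 = h | allele counts), h over `hets` (conditional distribution)
  logp <- vapply(hets, function(h) {
    hom1 <- (nR - h) %/% 2L
    hom2 <- n - h - hom1
    h * log(2) + lgamma(n + 1) - lgamma(hom1 + 1) - lgamma(h + 1) -
      lgamma(hom2 + 1) - (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(nB + 1))
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n12, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

.snpStats <- function(geno, idx) {
  g <- geno[, idx, drop = FALSE]
  miss <- rowMeans(is.na(g))
  n11 <- rowSums(g == 0L, na.rm = TRUE)
  n12 <- rowSums(g == 1L, na.rm = TRUE)
  n22 <- rowSums(g == 2L, na.rm = TRUE)
  tot <- n11 + n12 + n22
  f2 <- ifelse(tot > 0, (2 * n22 + n12) / (2 * tot), NA_real_)
  list(miss = miss, n11 = n11, n12 = n12, n22 = n22,
       maf = pmin(f2, 1 - f2), nMiss = rowSums(is.na(g)), n = ncol(g))
}

#' Apply SNP quality-control filters
#'
#' Removes SNPs with (i) significantly different missing-data rates between
#' cases and controls (two-sided Fisher exact test, p < 1e-5), (ii) overall
#' missing rate above 5\%, (iii) control minor allele frequency below 1\%, or
#' (iv) control genotypes out of Hardy-Weinberg equilibrium (exact test,
#' p < 1e-4).  MAF and HWE are computed on the controls only, since pedigree
#' cases are related.  Filters are evaluated independently on the input, so
#' the retained set does not depend on any ordering.
#'
#' @param genos a [SnpGenotypes-class] holding cases and controls together.
#' @param caseIds,controlIds sample id vectors partitioning the columns of
#'   interest (ids absent from `genos` raise an error).
#' @param thresholds named list overriding any of `diffMissP = 1e-5`,
#'   `missRate = 0.05`, `maf = 0.01`, `hweP = 1e-4`.
#' @param hweMethod passed to [hweTest()].
#' @return list with `genotypes` (the retained [SnpGenotypes-class]) and
#'   `report`, a data.frame with one row per input SNP: missing rates (cases,
#'   controls, combined), control MAF, HWE p, differential-missingness p, the
#'   `pass` flag and a semicolon-separated `reasons` string, plus an attached
#'   `"totals"` attribute counting removals per filter.
#' @export
filterSnps <- function(genos, caseIds, controlIds, thresholds = list(),
                       hweMethod = c("exact", "chisq")) {
  hweMethod <- match.arg(hweMethod)
  thr <- utils::modifyList(
    list(diffMissP = 1e-5, missRate = 0.05, maf = 0.01, hweP = 1e-4),
    thresholds)
  geno <- genoCodes(genos)
  absent <- setdiff(c(caseIds, controlIds), colnames(geno))
  if (length(absent))
    stop("sample id(s) not in genotype matrix: ",
         paste(absent, collapse = ", "))
  if (length(controlIds) == 0L)
    stop("MAF/HWE filters need a non-empty control set")
  ca <- .snpStats(geno, caseIds)
  co <- .snpStats(geno, controlIds)
  both <- .snpStats(geno, c(caseIds, controlIds))

  hweP <- vapply(seq_len(nrow(geno)), function(s) {
    if (co$n11[s] + co$n12[s] + co$n22[s] < 1L) return(1)
    hweTest(co$n11[s], co$n12[s], co$n22[s], method = hweMethod)
  }, numeric(1))

  diffP <- vapply(seq_len(nrow(geno)), function(s) {
    if (ca$nMiss[s] + co$nMiss[s] == 0L) return(1)
    stats::fisher.test(matrix(c(ca$nMiss[s], ca$n - ca$nMiss[s],
                                co$nMiss[s], co$n - co$nMiss[s]), 2L))$p.value
  }, numeric(1))

  fail <- cbind(diffMiss = diffP < thr$diffMissP,
                missRate = both$miss > thr$missRate,
                maf      = !is.na(co$maf) & co$maf < thr$maf,
                hwe      = hweP < thr$hweP)
  pass <- rowSums(fail) == 0L
  reasons <- apply(fail, 1L, function(f)
    paste(colnames(fail)[f], collapse = ";"))

  map <- snpInfo(genos)
  report <- data.frame(
    snpId = map$snpId, chr = map$chr, bp = map$bp,
    missCases = ca$miss, missControls = co$miss, missCombined = both$miss,
    mafControls = co$maf, hweP = hweP, diffMissP = diffP,
    pass = pass, reasons = reasons, stringsAsFactors = FALSE)
  attr(report, "totals") <- c(
    input = nrow(geno), retained = sum(pass),
    removedAny = sum(!pass), colSums(fail))
  list(genotypes = genos[pass, ], report = report)
}
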