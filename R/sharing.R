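## IBS sharing statistics: per-locus sharing counts S_i, run lengths,
## pairwise run lengths R_i^jk(2), the all-case SGS statistic R_i(N), the
## meiosis-weighted pairwise pSGS statistic, and the unweighted two-pedigree
## paired average.
##
## Genotype codes are allele-2 dosages (0 = "11", 1 = "12", 2 = "22",
## NA = missing).  Sharing is impossible only between opposite homozygotes;
## missing genotypes are treated as heterozygotes inside the sharing rules
## (and nowhere else).

#' Can two genotypes share an allele identical by state?
#'
#' `FALSE` exactly when the two codes are opposite homozygotes (0 and 2)
#' after mapping missing to heterozygote; `TRUE` otherwise.  Vectorized.
#'
#' @param a,b genotype codes (0/1/2/NA).
#' @return logical vector.
#' @export
pairShares <- function(a, b) {
  a[is.na(a)] <- 1L
  b[is.na(b)] <- 1L
  !((a == 0L & b == 2L) | (a == 2L & b == 0L))
}

#' Number of cases sharing an allele IBS at each locus
#'
#' S_i = N - min(N11_i, N22_i): every case outside the rarer opposite
#' homozygote class shares at least one allele with every other such case.
#' Missing genotypes count as heterozygotes, so S_i always lies in
#' [ceiling(N/2), N].
#'
#' @param geno dosage matrix (SNPs x cases) or a [SnpGenotypes-class].
#' @return integer vector of sharing counts.
#' @export
locusSharingCount <- function(geno) {
  if (is(geno, "SnpGenotypes")) geno <- genoCodes(geno)
  n11 <- rowSums(geno == 0L, na.rm = TRUE)
  n22 <- rowSums(geno == 2L, na.rm = TRUE)
  as.integer(ncol(geno) - pmin(n11, n22))
}

#' Per-locus run lengths of a sharing indicator
#'
#' For each locus, the number of consecutive SNPs (including the locus
#' itself) in the maximal contiguous block of `TRUE` containing it; 0 where
#' the indicator is `FALSE`.  Runs never span chromosome boundaries: pass
#' one chromosome at a time, or supply `chr` to split internally.
#'
#' @param share logical vector.
#' @param chr optional chromosome label per locus.
#' @return integer vector of run lengths.
#' @examples
#' runLengths(c(TRUE, TRUE, FALSE, TRUE))   # 2 2 0 1
#' @export
runLengths <- function(share, chr = NULL) {
  if (!is.null(chr)) {
    out <- integer(length(share))
    for (idx in split(seq_along(share), factor(chr, levels = unique(chr))))
      out[idx] <- runLengths(share[idx])
    return(out)
  }
  r <- rle(as.logical(share))
  rep.int(r$lengths * as.integer(r$values), r$lengths)
}

#' Pairwise IBS run lengths for all case pairs
#'
#' R_i^jk(2): for each unordered pair of cases (j, k) and each locus i, the
#' length of the maximal run of consecutive SNPs around i at which the pair
#' shares at least one allele IBS.
#'
#' @param geno dosage matrix (SNPs x cases) or [SnpGenotypes-class].
#' @param chr chromosome label per locus (taken from the object when a
#'   [SnpGenotypes-class] is supplied).
#' @return integer matrix (SNPs x pairs); the pair order is
#'   (1,2), (1,3), ..., (N-1,N) over the case columns, with an attached
#'   `"pairs"` attribute giving the column indices.
#' @export
pairwiseRunLengths <- function(geno, chr = NULL) {
  if (is(geno, "SnpGenotypes")) {
    if (is.null(chr)) chr <- snpInfo(geno)$chr
    geno <- genoCodes(geno)
  }
  N <- ncol(geno)
  pr <- .pairIndex(N)
  out <- matrix(0L, nrow(geno), ncol(pr))
  for (p in seq_len(ncol(pr))) {
    share <- pairShares(geno[, pr[1L, p]], geno[, pr[2L, p]])
    out[, p] <- runLengths(share, chr)
  }
  attr(out, "pairs") <- pr
  out
}

#' Weighted pairwise SGS statistic
#'
#' The pSGS statistic at each locus: the mean of the pairwise run lengths
#' R_i^jk(2) over all case pairs, weighted by each pair's meiosis count
#' d_jk — sharing across more meioses is more surprising and so counts for
#' more.  Any overall rescaling of the weights leaves the statistic (and
#' every empirical p-value built on it) unchanged.
#'
#' @param pairRuns matrix (SNPs x pairs) from [pairwiseRunLengths()].
#' @param d numeric vector of pair weights (meiosis counts), one per column.
#' @return numeric vector: `pairRuns %*% d / sum(d)`.
#' @export
psgsStatistic <- function(pairRuns, d) {
  if (ncol(pairRuns) != length(d))
    stop("weights do not match the pair columns (", ncol(pairRuns),
         " pairs, ", length(d), " weights)")
  as.numeric(pairRuns %*% d) / sum(d)
}

#' All-case SGS statistic
#'
#' R_i(N): the run length of consecutive SNPs at which all N cases share at
#' least one allele IBS (S_i = N).
#'
#' @inheritParams pairwiseRunLengths
#' @param t sharing threshold; defaults to all cases (N).
#' @return integer vector of run lengths.
#' @export
sgsStatistic <- function(geno, chr = NULL, t = NULL) {
  if (is(geno, "SnpGenotypes")) {
    if (is.null(chr)) chr <- snpInfo(geno)$chr
    geno <- genoCodes(geno)
  }
  if (is.null(t)) t <- ncol(geno)
  S <- locusSharingCount(geno)
  runLengths(S >= t, chr)
}

#' Unweighted paired-average statistic for cases pooled across pedigrees
#'
#' When cases come from pedigrees with no known genealogical links, pairwise
#' sharing cannot be weighted by meiosis counts, so the statistic is the
#' plain mean of R_i^jk(2) over all unordered pairs of the combined case
#' set (within- and cross-pedigree pairs alike).
#'
#' @inheritParams pairwiseRunLengths
#' @return numeric vector per locus.
#' @export
twoPedigreeStatistic <- function(geno, chr = NULL) {
  runs <- pairwiseRunLengths(geno, chr)
  psgsStatistic(runs, rep(1, ncol(runs)))
}

#' Compute the full sharing profile of a pedigree's cases
#'
#' @param genos a [SnpGenotypes-class] whose columns include all case ids of
#'   `ped` (extra columns are ignored), or a [GeneDrop-class].
#' @param ped the [Pedigree-class] the cases belong to.
#' @return a [SharingProfile-class] with S_i, pairwise run lengths, and the
#'   pSGS and SGS tracks.
#' @export
sharingProfile <- function(genos, ped) {
  if (is(genos, "GeneDrop")) {
    geno <- caseGenotypes(genos)
    map <- genos@map
  } else {
    map <- snpInfo(genos)
    geno <- genoCodes(genos)
  }
  ids <- caseIds(ped)
  missing <- setdiff(ids, colnames(geno))
  if (length(missing))
    stop("genotypes lack case(s): ", paste(missing, collapse = ", "))
  geno <- geno[, ids, drop = FALSE]
  pt <- pairTable(ped)
  runs <- pairwiseRunLengths(geno, map$chr)
  new("SharingProfile",
      map = map,
      S = locusSharingCount(geno),
      pairRuns = runs,
      pairs = pt,
      psgs = psgsStatistic(runs, pt$d),
      sgs = sgsStatistic(geno, map$chr),
      caseIds = ids)
}

#' @rdname SharingProfile-class
#' @export
setMethod("sharingCounts", "SharingProfile", function(x) x@S)

#' @rdname SharingProfile-class
#' @export
setMethod("psgsTrack", "SharingProfile", function(x) x@psgs)

#' @rdname SharingProfile-class
#' @export
setMethod("sgsTrack", "SharingProfile", function(x) x@sgs)

#' @rdname SharingProfile-class
#' @export
setMethod("pairRuns", "SharingProfile", function(x) x@pairRuns)

setMethod("show", "SharingProfile", function(object) {
  cat("SharingProfile: ", length(object@S), " SNPs, ",
      length(object@caseIds), " cases, ", nrow(object@pairs), " pairs\n",
      "  S range ", min(object@S), "-", max(object@S),
      "; max pSGS ", sprintf("%.1f", max(object@psgs)),
      "; max SGS ", max(object@sgs), "\n", sep = "")
})

#' Summarize sharing counts over a region's loci
#'
#' @param S integer sharing counts (from [locusSharingCount()] or
#'   [sharingCounts()]).
#' @param loci integer indices of the region's loci.
#' @return named numeric vector `mean`, `min`, `max`.
#' @export
regionSharingSummary <- function(S, loci) {
  if (!length(loci)) stop("empty locus set")
  c(mean = mean(S[loci]), min = min(S[loci]), max = max(S[loci]))
}
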