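## Empirical significance machinery: gene-dropping null stores, per-locus
## empirical p-values, nominal region calling, mu (findings-per-genome)
## rates and empirical genomewide suggestive/significant thresholds.

## Statistic track for one genotype configuration of the cases.
.statTrack <- function(geno, chr, statistic, weights = NULL) {
  switch(statistic,
    psgs = psgsStatistic(pairwiseRunLengths(geno, chr), weights),
    sgs = as.numeric(sgsStatistic(geno, chr)),
    twoPed = twoPedigreeStatistic(geno, chr),
    stop("unknown statistic '", statistic, "'"))
}

#' Simulate a null statistic store by gene dropping
#'
#' Generates `n` null genotype configurations for the pedigree's cases
#' (founder haplotypes from the LD model, Mendelian segregation with
#' genetic-map recombination) and records the chosen sharing statistic at
#' every locus, giving each locus its own null distribution.
#'
#' For the two-pedigree statistic pass a list of two pedigrees: each is
#' gene-dropped independently from the same LD model per replicate and the
#' unweighted paired average is computed over the combined case set.
#'
#' When `maskFrom` (observed case genotypes) is supplied, null genotypes are
#' set missing wherever the observed data are missing before the statistic
#' is computed, so observed and null tracks are treated identically under
#' the missing-as-heterozygote convention.
#'
#' @param ped a [Pedigree-class], or list of two for `statistic = "twoPed"`.
#' @param model a [HaplotypeLDModel-class].
#' @param map data.frame marker map.
#' @param n number of null replicates.
#' @param statistic `"psgs"`, `"sgs"` or `"twoPed"`.
#' @param seed master seed; replicate r uses a seed derived from it.
#' @param maskFrom optional observed dosage matrix (SNPs x cases) whose
#'   missingness pattern is copied onto every null replicate.
#' @return a [NullStatisticStore-class].
#' @export
simulateNullStatistics <- function(ped, model, map, n,
                                   statistic = c("psgs", "sgs", "twoPed"),
                                   seed = NULL, maskFrom = NULL) {
  statistic <- match.arg(statistic)
  peds <- if (is(ped, "Pedigree")) list(ped) else ped
  if (statistic == "twoPed" && length(peds) != 2L)
    stop("two-pedigree statistic needs a list of two pedigrees")
  weights <- if (statistic == "psgs") pairTable(peds[[1L]])$d
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  vals <- matrix(NA_real_, n, nrow(map))
  for (r in seq_len(n)) {
    .seedRNG(deriveSeed(seed, r))
    geno <- do.call(cbind, lapply(peds, function(p)
      caseGenotypes(dropGenome(p, model, map))))
    if (!is.null(maskFrom)) geno[is.na(maskFrom)] <- NA_integer_
    vals[r, ] <- .statTrack(geno, map$chr, statistic, weights)
  }
  new("NullStatisticStore", values = vals, statistic = statistic,
      map = as.data.frame(map), seed = seed)
}

#' @rdname NullStatisticStore-class
#' @export
setMethod("nullValues", "NullStatisticStore", function(x) x@values)

setMethod("show", "NullStatisticStore", function(object) {
  cat("NullStatisticStore: ", nrow(object@values), " replicates x ",
      ncol(object@values), " loci (", object@statistic, ")\n", sep = "")
})

#' Empirical p-value against a null collection
#'
#' p = (1 + #\{null >= observed\}) / (1 + n): the add-one correction keeps
#' p strictly positive with finitely many replicates.
#'
#' @param observed observed statistic value.
#' @param nulls numeric vector of null values.
#' @return p-value in (0, 1].
#' @export
empiricalP <- function(observed, nulls) {
  if (!length(nulls)) stop("empty null collection")
  (1 + sum(nulls >= observed)) / (1 + length(nulls))
}

#' Per-locus empirical p-values of an observed track
#'
#' @param observed numeric statistic track (or a [SharingProfile-class],
#'   from which the track matching the store's statistic is taken).
#' @param store a [NullStatisticStore-class].
#' @return numeric p-value vector, one per locus.
#' @export
locusPValues <- function(observed, store) {
  if (is(observed, "SharingProfile"))
    observed <- switch(store@statistic,
                       psgs = psgsTrack(observed),
                       sgs = as.numeric(sgsTrack(observed)),
                       stop("supply a numeric track for statistic '",
                            store@statistic, "'"))
  vals <- nullValues(store)
  if (length(observed) != ncol(vals))
    stop("observed track and null store disagree on locus count")
  n <- nrow(vals)
  cnt <- colSums(vals >= matrix(observed, n, length(observed), byrow = TRUE))
  (1 + cnt) / (1 + n)
}

#' Call nominal regions from a per-locus p-value track
#'
#' A region is a maximal run of consecutive loci with p <= alpha on one
#' chromosome.  Bounds are the bp positions of the first and last nominal
#' locus; the reported length in Mb is (end - start) / 1e6 rounded to one
#' decimal.
#'
#' @param p numeric p-value track aligned to `map`.
#' @param map data.frame marker map (chr, snpId, bp, cM), sorted by
#'   chromosome and bp.
#' @param alpha nominal level (default 0.05).
#' @param S optional sharing counts for per-region sharing summaries.
#' @return a [GenomicRanges::GRanges] with metadata columns `nSnps`,
#'   `lengthMb`, `bestP`, `startIdx`, `endIdx` and, when `S` is given,
#'   `meanSharing`, `minSharing`, `maxSharing`.  Empty when no locus is
#'   nominal.
#' @export
callRegions <- function(p, map, alpha = 0.05, S = NULL) {
  .checkMap(map)
  if (length(p) != nrow(map))
    stop("p track and map disagree on locus count")
  rows <- list()
  for (idx in .chrSplit(map)) {
    sig <- p[idx] <= alpha
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      gi <- idx[starts[b]:ends[b]]
      rows[[length(rows) + 1L]] <- data.frame(
        chr = as.character(map$chr[gi[1L]]),
        startBp = map$bp[gi[1L]], endBp = map$bp[gi[length(gi)]],
        nSnps = length(gi), bestP = min(p[gi]),
        startIdx = gi[1L], endIdx = gi[length(gi)])
    }
  }
  if (!length(rows))
    return(GRanges(seqnames = character(0),
                   ranges = IRanges(start = integer(0), end = integer(0))))
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chr, IRanges(df$startBp, df$endBp))
  mcols(gr) <- S4Vectors::DataFrame(
    nSnps = df$nSnps,
    lengthMb = round((df$endBp - df$startBp) / 1e6, 1),
    bestP = df$bestP, startIdx = df$startIdx, endIdx = df$endIdx)
  if (!is.null(S)) {
    sh <- t(vapply(seq_along(gr), function(i)
      regionSharingSummary(S, df$startIdx[i]:df$endIdx[i]), numeric(3)))
    mcols(gr)$meanSharing <- unname(sh[, 1L])
    mcols(gr)$minSharing <- as.integer(sh[, 2L])
    mcols(gr)$maxSharing <- as.integer(sh[, 3L])
  }
  gr
}

#' Intersect two sets of region calls
#'
#' Pairwise intersections of overlapping regions on the same chromosome:
#' bounds are [max(starts), min(ends)] and the Mb length is recomputed.
#' Disjoint inputs give an empty result; intersecting two single regions on
#' different chromosomes is an error.
#'
#' @param a,b [GenomicRanges::GRanges] region calls (e.g. from
#'   [callRegions()]).
#' @return a [GenomicRanges::GRanges] with `lengthMb` and, when present in
#'   the inputs, `bestP.a` / `bestP.b`.
#' @export
intersectRegions <- function(a, b) {
  if (length(a) == 1L && length(b) == 1L &&
      as.character(seqnames(a)) != as.character(seqnames(b)))
    stop("regions lie on different chromosomes")
  hits <- findOverlaps(a, b)
  if (!length(hits))
    return(GRanges(seqnames = character(0),
                   ranges = IRanges(start = integer(0), end = integer(0))))
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  gr <- pintersect(a[ai], b[bi], drop.nohit.ranges = TRUE)
  mcols(gr) <- NULL
  mcols(gr)$lengthMb <- round((end(gr) - start(gr)) / 1e6, 1)
  if (!is.null(mcols(a)$bestP)) mcols(gr)$bestP.a <- mcols(a)$bestP[ai]
  if (!is.null(mcols(b)$bestP)) mcols(gr)$bestP.b <- mcols(b)$bestP[bi]
  gr
}

#' Rank-based threshold from pooled null segment p-values
#'
#' With G null genomes, the p-value level crossed at a target rate of `rate`
#' findings per genome is the value at ascending rank `round(rate * G)` of
#' the pooled segment p-values (rank 50 of 1,000 genomes for rate 0.05;
#' rank 1,000 for rate 1).
#'
#' @param pooled numeric vector of null segment p-values pooled across
#'   genomes.
#' @param G number of null genomes that produced them.
#' @param rate target findings-per-genome rate.
#' @return the threshold p-value, or `NA` (with a warning) when the pooled
#'   list is shorter than the required rank.
#' @export
rankThreshold <- function(pooled, G, rate) {
  r <- round(rate * G)
  if (r < 1L) r <- 1L
  if (r > length(pooled)) {
    warning("threshold undefined: pooled list has ", length(pooled),
            " segment p-values but rank ", r, " is required")
    return(NA_real_)
  }
  sort(pooled)[r]
}

#' Empirical genomewide suggestive and significant thresholds
#'
#' Simulates `G` null genome configurations for the pedigree; for each,
#' computes the statistic track, converts it to per-locus empirical
#' p-values against an inner null store, calls nominal regions and records
#' each region's p-value (its minimum per-locus p).  The pooled, ranked
#' segment p-values give the thresholds: the rate-0.05 rank (genomewide
#' significant) and the rate-1.0 rank (genomewide suggestive).
#'
#' By default one inner null store serves all `G` outer genomes;
#' `freshInner = TRUE` re-simulates it per genome (far more costly).
#'
#' @param ped,model,map as in [simulateNullStatistics()].
#' @param G number of outer null genomes (>= 20).
#' @param nInner inner replicate count for the per-locus null store.
#' @param statistic `"psgs"` or `"sgs"`.
#' @param alpha nominal level used for region calling.
#' @param seed master seed.
#' @param innerStore optional pre-built [NullStatisticStore-class].
#' @param freshInner re-simulate the inner store for every outer genome.
#' @return list with `suggestive`, `significant`, `pooled` (all segment
#'   p-values), `G`, `statistic`, `alpha`, `segmentsPerGenome`.
#' @export
genomewideThresholds <- function(ped, model, map, G, nInner = 199L,
                                 statistic = c("psgs", "sgs"), alpha = 0.05,
                                 seed = NULL, innerStore = NULL,
                                 freshInner = FALSE) {
  statistic <- match.arg(statistic)
  if (G < 20L) stop("G must be at least 20")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (is.null(innerStore) && !freshInner)
    innerStore <- simulateNullStatistics(ped, model, map, nInner, statistic,
                                         seed = deriveSeed(seed, 0L))
  weights <- if (statistic == "psgs") pairTable(ped)$d
  pooled <- numeric(0)
  nseg <- integer(G)
  for (g in seq_len(G)) {
    if (freshInner)
      innerStore <- simulateNullStatistics(
        ped, model, map, nInner, statistic,
        seed = deriveSeed(seed, G + g))
    .seedRNG(deriveSeed(seed, g))
    geno <- caseGenotypes(dropGenome(ped, model, map))
    track <- .statTrack(geno, map$chr, statistic, weights)
    p <- locusPValues(track, innerStore)
    regions <- callRegions(p, map, alpha = alpha)
    nseg[g] <- length(regions)
    if (length(regions)) pooled <- c(pooled, mcols(regions)$bestP)
  }
  list(suggestive = rankThreshold(pooled, G, 1.0),
       significant = rankThreshold(pooled, G, 0.05),
       pooled = pooled, G = G, statistic = statistic, alpha = alpha,
       segmentsPerGenome = mean(nseg))
}

#' Findings-per-genome rate of an observed region p-value
#'
#' mu = #\{pooled null segment p <= observed p\} / G: the number of null
#' findings per genome at least as extreme as the observed one (mu = 0.98
#' means such a region is expected 0.98 times per genome under the null).
#'
#' @param observedP observed region p-value.
#' @param pooled pooled null segment p-values (from
#'   [genomewideThresholds()]).
#' @param G number of null genomes.
#' @return mu rate (non-negative real).
#' @export
muRate <- function(observedP, pooled, G) {
  sum(pooled <= observedP) / G
}

#' Export region calls as BED and/or TSV
#'
#' BED output is 0-based half-open with score = -log10(best p); the TSV
#' mirrors the region table (chromosome, 1-based bounds, length in Mb, best
#' p, sharing summary and mu when present).
#'
#' @param regions a [GenomicRanges::GRanges] from [callRegions()].
#' @param bedPath,tsvPath output paths (`NULL` to skip).
#' @return invisibly, the written paths.
#' @export
exportRegions <- function(regions, bedPath = NULL, tsvPath = NULL) {
  written <- character(0)
  df <- as.data.frame(regions)
  if (!is.null(bedPath)) {
    score <- if (!is.null(df$bestP)) -log10(df$bestP) else rep(0, nrow(df))
    bed <- data.frame(chrom = df$seqnames, start = df$start - 1L,
                      end = df$end,
                      name = paste0("region_", seq_len(nrow(df))),
                      score = round(score, 4))
    utils::write.table(bed, bedPath, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, bedPath)
  }
  if (!is.null(tsvPath)) {
    tsv <- data.frame(chr = df$seqnames,
                      region = paste(df$start, "-", df$end),
                      lengthMb = df$lengthMb, bestP = df$bestP)
    for (col in c("meanSharing", "minSharing", "maxSharing", "mu"))
      if (!is.null(df[[col]])) tsv[[col]] <- df[[col]]
    utils::write.table(tsv, tsvPath, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    written <- c(written, tsvPath)
  }
  invisible(written)
}
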