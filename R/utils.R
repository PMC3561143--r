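## Internal helpers shared across modules.

## Set the RNG from `seed` when given; NULL leaves the caller's RNG state.
.seedRNG <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

## Deterministic per-replicate seed derivation from a master seed, kept
## inside 32-bit integer range so set.seed() accepts it.
deriveSeed <- function(master, i) {
  as.integer((as.numeric(master) * 69069 + 12345 * as.numeric(i)) %% 2147483647)
}

## Validate a marker map data.frame: required columns, per-chromosome
## ordering (bp strictly increasing, cM non-decreasing), chromosomes in
## contiguous blocks.
.checkMap <- function(map, requireAlleles = FALSE) {
  need <- c("chr", "snpId", "bp", "cM")
  if (requireAlleles) need <- c(need, "allele1", "allele2")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("marker map lacks column(s): ", paste(miss, collapse = ", "))
  chr <- as.character(map$chr)
  r <- rle(chr)
  if (anyDuplicated(r$values))
    stop("chromosomes must occupy contiguous blocks of the marker map")
  for (idx in split(seq_len(nrow(map)), factor(chr, levels = r$values))) {
    if (is.unsorted(map$bp[idx], strictly = TRUE))
      stop("bp positions must be strictly increasing within chromosome ",
           chr[idx[1]])
    if (is.unsorted(map$cM[idx]))
      stop("cM positions must be non-decreasing within chromosome ",
           chr[idx[1]])
  }
  invisible(map)
}

## Row indices of the map split by chromosome, preserving file order.
.chrSplit <- function(map) {
  chr <- as.character(map$chr)
  split(seq_along(chr), factor(chr, levels = unique(chr)))
}

## All unordered pairs 1..n as a 2-row index matrix (j < k), column-major in
## the conventional nested order (1,2), (1,3), ..., (n-1,n).
.pairIndex <- function(n) {
  if (n < 2L) stop("need at least two elements to form pairs")
  utils::combn(n, 2L)
}
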