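## Gene-dropping Monte Carlo: founder haplotypes from the LD model are
## segregated through the pedigree under Mendelian inheritance, with
## crossovers as a homogeneous Poisson process on the genetic-map (cM) axis
## (rate 1 per Morgan, no interference).

## Pedigree bookkeeping for transmission: integer parent indices and a
## topological order with parents before children.
.pedStruct <- function(ped) {
  ind <- ped@individuals
  ids <- ind$id
  fa <- match(ind$father, ids)
  mo <- match(ind$mother, ids)
  n <- length(ids)
  placed <- logical(n)
  topo <- integer(0)
  while (length(topo) < n) {
    okF <- is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]
    okM <- is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)]
    free <- which(!placed & okF & okM)
    if (!length(free)) stop("pedigree is not acyclic")
    placed[free] <- TRUE
    topo <- c(topo, free)
  }
  founders <- which(is.na(fa))
  list(ids = ids, fa = fa, mo = mo, topo = topo, founders = founders,
       founderSlot = match(seq_len(n), founders),
       caseIdx = match(caseIds(ped), ids))
}

## Crossover origins along one chromosome: which parental haplotype (1 or 2)
## each SNP's allele is copied from.
.gameteOrigin <- function(cM) {
  span <- (max(cM) - min(cM)) / 100      # Morgans
  nx <- stats::rpois(1L, span)
  start <- sample.int(2L, 1L)
  if (nx == 0L) return(rep.int(start, length(cM)))
  pos <- sort(stats::runif(nx, min(cM), max(cM)))
  1L + (start - 1L + findInterval(cM, pos)) %% 2L
}

#' Sample one gamete from a pair of parental haplotypes
#'
#' Crossover points are drawn as a Poisson process with rate 1 per Morgan
#' along the cM axis (Haldane model, no interference); the starting
#' haplotype is chosen with probability 1/2 and alleles are copied from the
#' active haplotype, switching at each crossover.
#'
#' @param haps matrix (SNPs x 2) of parental haplotype alleles.
#' @param cM numeric vector of map positions (non-decreasing).
#' @param labels optional matrix (SNPs x 2) of founder-gamete labels riding
#'   along with the alleles.
#' @return list with `alleles` (integer vector), `origin` (1/2 per SNP:
#'   which parental haplotype was copied) and, when `labels` was supplied,
#'   `labels`.
#' @export
sampleGamete <- function(haps, cM, labels = NULL) {
  haps <- as.matrix(haps)
  if (nrow(haps) != length(cM))
    stop("haplotypes and map cover different SNP counts")
  o <- .gameteOrigin(cM)
  pick <- cbind(seq_along(cM), o)
  out <- list(alleles = haps[pick], origin = o)
  if (!is.null(labels)) out$labels <- as.matrix(labels)[pick]
  out
}

## Segregate one chromosome by propagating founder-gamete labels (founder f
## contributes gametes 2f-1 and 2f) through the transmission graph; the
## label track determines the alleles, so only labels are propagated.
## Returns the case label matrices.  Exposed internally so the
## synthetic-data generator can resample transmissions while holding
## founder haplotypes fixed.
##
## `force` (optional) conditions designated transmissions to carry a given
## founder gamete at one locus: list(locus = local SNP index, gam = gamete
## label, edges = 2-column matrix of (child index, side) with side 1 =
## paternal, 2 = maternal).  The crossover process of a forced transmission
## is sampled unconditionally and the whole origin vector flipped when it
## does not deliver the required gamete at the locus — a measure-preserving
## map between the two conditionings, so the conditional recombination law
## is exact.
.dropChromosome <- function(struct, cM, force = NULL) {
  m <- length(cM)
  n <- length(struct$ids)
  L <- matrix(0L, m, 2L * n)
  rows <- seq_len(m)
  forced <- if (!is.null(force))
    paste(force$edges[, 1L], force$edges[, 2L])
  for (i in struct$topo) {
    c1 <- 2L * i - 1L; c2 <- 2L * i
    if (is.na(struct$fa[i])) {                     # founder
      slot <- struct$founderSlot[i]
      L[, c1] <- 2L * slot - 1L
      L[, c2] <- 2L * slot
    } else {
      for (side in 1:2) {
        p <- if (side == 1L) struct$fa[i] else struct$mo[i]
        o <- .gameteOrigin(cM)
        if (!is.null(force) && paste(i, side) %in% forced) {
          pc <- 2L * (p - 1L)
          need <- which(L[force$locus, pc + 1:2] == force$gam)
          if (length(need) != 1L)
            stop("forced transmission: parent does not carry the risk ",
                 "gamete exactly once at the locus")
          if (o[force$locus] != need) o <- 3L - o
        }
        tgt <- if (side == 1L) c1 else c2
        L[, tgt] <- L[cbind(rows, 2L * (p - 1L) + o)]
      }
    }
  }
  ci <- struct$caseIdx
  list(L1 = L[, 2L * ci - 1L, drop = FALSE],
       L2 = L[, 2L * ci, drop = FALSE])
}

## Case dosage matrix from founder haplotypes and transmitted labels.
.genoFromLabels <- function(founderHaps, L1, L2) {
  rows <- seq_len(nrow(L1))
  g <- matrix(0L, nrow(L1), ncol(L1))
  for (j in seq_len(ncol(L1)))
    g[, j] <- (founderHaps[cbind(rows, L1[, j])] - 1L) +
              (founderHaps[cbind(rows, L2[, j])] - 1L)
  g
}

#' Gene-drop a whole genome through a pedigree
#'
#' Every founder receives two haplotypes sampled from the LD model; every
#' non-founder receives one recombinant gamete from each parent; genotypes
#' are retained for the cases only.  Chromosomes segregate independently.
#' With `traceIBD = TRUE` each transmitted allele carries the label of the
#' founder gamete it descends from, which makes identity-by-descent segments
#' directly observable.
#'
#' @param ped a [Pedigree-class].
#' @param model a [HaplotypeLDModel-class] covering the map's SNPs (may be
#'   `NULL` when `genotypes = FALSE`).
#' @param map data.frame marker map (`chr`, `snpId`, `bp`, `cM`); defaults
#'   to the model's SNPs with the cM/bp stored there being required.
#' @param seed optional integer seed.
#' @param traceIBD keep founder-gamete labels per transmitted allele.
#' @param genotypes compute allele/dosage matrices (turn off for pure IBD
#'   bookkeeping, which does not need founder haplotypes).
#' @return a [GeneDrop-class].
#' @export
dropGenome <- function(ped, model, map, seed = NULL, traceIBD = FALSE,
                       genotypes = TRUE) {
  .seedRNG(seed)
  .checkMap(map)
  struct <- .pedStruct(ped)
  nF <- length(struct$founders)
  chrIdx <- .chrSplit(map)
  if (genotypes) {
    if (is.null(model)) stop("genotypes require an LD model")
    for (chr in names(chrIdx)) {
      ch <- model@chrom[[chr]]
      if (is.null(ch)) stop("LD model lacks chromosome '", chr, "'")
      if (!identical(as.character(ch$snpId),
                     as.character(map$snpId[chrIdx[[chr]]])))
        stop("LD model and map disagree on the SNPs of chromosome ", chr)
    }
  }
  m <- nrow(map)
  N <- nCases(ped)
  geno <- if (genotypes) matrix(NA_integer_, m, N,
                                dimnames = list(map$snpId, caseIds(ped)))
  lab1 <- if (traceIBD) matrix(0L, m, N,
                               dimnames = list(map$snpId, caseIds(ped)))
  lab2 <- if (traceIBD) lab1
  for (chr in names(chrIdx)) {
    idx <- chrIdx[[chr]]
    fh <- if (genotypes) sampleHaplotype(model, chr, n = 2L * nF)
    res <- .dropChromosome(struct, map$cM[idx])
    if (genotypes) geno[idx, ] <- .genoFromLabels(fh, res$L1, res$L2)
    if (traceIBD) { lab1[idx, ] <- res$L1; lab2[idx, ] <- res$L2 }
  }
  new("GeneDrop", geno = geno, lab1 = lab1, lab2 = lab2,
      map = as.data.frame(map), caseIds = caseIds(ped))
}

#' @rdname GeneDrop-class
#' @export
setMethod("caseGenotypes", "GeneDrop", function(x) x@geno)

#' @rdname GeneDrop-class
#' @export
setMethod("ibdLabels", "GeneDrop", function(x) list(lab1 = x@lab1,
                                                    lab2 = x@lab2))

setMethod("show", "GeneDrop", function(object) {
  cat("GeneDrop: ", nrow(object@map), " SNPs x ", length(object@caseIds),
      " cases", if (!is.null(object@lab1)) " (IBD traced)",
      if (is.null(object@geno)) " (labels only)", "\n", sep = "")
})

#' Write the founder-gamete IBD trace of a gene drop as TSV
#'
#' One row per SNP: chromosome, SNP id, bp, then two columns per case with
#' the founder-gamete labels of its paternally and maternally transmitted
#' alleles.
#'
#' @param drop a [GeneDrop-class] produced with `traceIBD = TRUE`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeIbdTrace <- function(drop, path) {
  if (is.null(drop@lab1)) stop("gene drop was made without traceIBD")
  out <- data.frame(chr = drop@map$chr, snpId = drop@map$snpId,
                    bp = drop@map$bp)
  for (j in seq_along(drop@caseIds)) {
    out[[paste0(drop@caseIds[j], ".pat")]] <- drop@lab1[, j]
    out[[paste0(drop@caseIds[j], ".mat")]] <- drop@lab2[, j]
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Maximal IBD-shared segments between two cases of a gene drop
#'
#' For each founder gamete carried by both cases, the maximal runs of
#' consecutive SNPs at which both carry that gamete.  Segment boundaries are
#' placed at the midpoints between the last shared SNP and its non-shared
#' neighbour (chromosome ends when the run touches them), so interior
#' segment lengths estimate the underlying crossover interval without a
#' systematic half-spacing bias.
#'
#' @param drop a [GeneDrop-class] produced with `traceIBD = TRUE`.
#' @param case1,case2 case identifiers.
#' @param by `"gamete"` (default): one segment set per shared founder
#'   gamete; `"any"`: runs of the union indicator (sharing any gamete).
#' @return data.frame with columns `chr`, `gamete` (`NA` for `by = "any"`),
#'   `startIdx`, `endIdx`, `lengthCM` and `truncated` (run touches a
#'   chromosome end).
#' @export
ibdSegments <- function(drop, case1, case2, by = c("gamete", "any")) {
  by <- match.arg(by)
  if (is.null(drop@lab1)) stop("gene drop was made without traceIBD")
  j <- match(as.character(case1), drop@caseIds)
  k <- match(as.character(case2), drop@caseIds)
  if (is.na(j) || is.na(k)) stop("unknown case id")
  chrIdx <- .chrSplit(drop@map)
  out <- list()
  for (chr in names(chrIdx)) {
    idx <- chrIdx[[chr]]
    cM <- drop@map$cM[idx]
    m <- length(idx)
    A1 <- drop@lab1[idx, j]; A2 <- drop@lab2[idx, j]
    B1 <- drop@lab1[idx, k]; B2 <- drop@lab2[idx, k]
    runsOf <- function(ind, gamete) {
      r <- rle(ind)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      if (!any(keep)) return(NULL)
      s <- starts[keep]; e <- ends[keep]
      lo <- (cM[s] + cM[pmax(s - 1L, 1L)]) / 2
      lo[s == 1L] <- cM[1L]
      hi <- (cM[e] + cM[pmin(e + 1L, m)]) / 2
      hi[e == m] <- cM[m]
      data.frame(chr = chr, gamete = gamete, startIdx = s, endIdx = e,
                 lengthCM = hi - lo, truncated = s == 1L | e == m,
                 stringsAsFactors = FALSE)
    }
    if (by == "any") {
      ind <- (A1 == B1) | (A1 == B2) | (A2 == B1) | (A2 == B2)
      out[[length(out) + 1L]] <- runsOf(ind, NA_integer_)
    } else {
      gams <- intersect(unique(c(A1, A2)), unique(c(B1, B2)))
      for (g in gams) {
        ind <- (A1 == g | A2 == g) & (B1 == g | B2 == g)
        out[[length(out) + 1L]] <- runsOf(ind, g)
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chr = character(0), gamete = integer(0),
                      startIdx = integer(0), endIdx = integer(0),
                      lengthCM = numeric(0), truncated = logical(0)))
  do.call(rbind, out)
}
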