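## Order-k Markov haplotype model of linkage disequilibrium: estimation from
## unrelated control genotypes by windowed haplotype-frequency EM, founder
## haplotype sampling, and plain-text serialization.
##
## Haplotypes over a window of w SNPs are encoded as integers 0..2^w-1 with
## bit j set when the allele at window position j is allele 2.  Multilocus
## genotype patterns are encoded base-3 (digit j = allele-2 dosage).

## For each genotype pattern of width w, the ordered haplotype pairs
## consistent with it: h2 = h1 XOR hetmask.  Returned as a list indexed by
## pattern code + 1.
.patternPairs <- function(w) {
  npat <- 3L^w
  out <- vector("list", npat)
  for (p in seq_len(npat) - 1L) {
    digits <- (p %/% 3L^(seq_len(w) - 1L)) %% 3L
    base <- sum(2L^(which(digits == 2L) - 1L))
    hetpos <- which(digits == 1L)
    hetmask <- sum(2L^(hetpos - 1L))
    if (length(hetpos) == 0L) {
      h1 <- base
    } else {
      sub <- 0L
      h1 <- integer(2L^length(hetpos))
      for (i in seq_along(h1)) {
        bits <- (i - 1L)
        h1[i] <- base + sum(2L^(hetpos[bitwAnd(bitwShiftR(bits,
                    seq_along(hetpos) - 1L), 1L) == 1L] - 1L))
      }
    }
    out[[p + 1L]] <- cbind(h1 = h1, h2 = bitwXor(h1, hetmask))
  }
  out
}

## Haplotype-frequency EM for one window from tabulated pattern counts.
## Returns list(freq, logLikTrace, iterations, converged).
.emWindow <- function(patCounts, w, pairs, tol = 1e-6, maxIter = 500L,
                      init = NULL) {
  nh <- 2L^w
  codes <- as.integer(names(patCounts))
  counts <- as.numeric(patCounts)
  nInd <- sum(counts)
  if (nInd == 0)
    return(list(freq = rep(1 / nh, nh), logLikTrace = numeric(0),
                iterations = 0L, converged = TRUE))
  f <- if (is.null(init)) rep(1 / nh, nh) else init
  llTrace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    newCounts <- numeric(nh)
    ll <- 0
    for (i in seq_along(codes)) {
      pr <- pairs[[codes[i] + 1L]]
      wts <- f[pr[, 1L] + 1L] * f[pr[, 2L] + 1L]
      tot <- sum(wts)
      if (tot <= 0) { wts <- rep(1 / nrow(pr), nrow(pr)); tot <- 1 }
      else wts <- wts / tot
      ll <- ll + counts[i] * log(max(tot, .Machine$double.xmin))
      add <- counts[i] * wts
      for (col in 1:2) {
        idx <- pr[, col] + 1L
        newCounts[idx] <- newCounts[idx] + add
      }
    }
    llTrace <- c(llTrace, ll)
    fNew <- newCounts / (2 * nInd)
    if (max(abs(fNew - f)) < tol) { f <- fNew; converged <- TRUE; break }
    f <- fNew
  }
  list(freq = f, logLikTrace = llTrace, iterations = it,
       converged = converged)
}

## Linkage-equilibrium initial haplotype frequencies for a window from
## observed per-SNP allele-2 frequencies.
.leInit <- function(freq2) {
  w <- length(freq2)
  nh <- 2L^w
  f <- rep(1, nh)
  for (j in seq_len(w)) {
    bit <- bitwAnd(bitwShiftR(seq_len(nh) - 1L, j - 1L), 1L)
    f <- f * ifelse(bit == 1L, freq2[j], 1 - freq2[j])
  }
  f
}

#' Fit a Markov haplotype LD model from unrelated controls
#'
#' Estimates, per chromosome, an order-`k` Markov chain over alleles by
#' expectation-maximization of haplotype frequencies in sliding windows of
#' `k + 1` adjacent SNPs (for `k = 1`, classical two-locus EM resolving the
#' double-heterozygote phase ambiguity), then normalizing window frequencies
#' to transition distributions.  Expected haplotype counts receive a
#' pseudocount (0.5 per class by default) so no transition probability is
#' exactly 0 or 1 unless forced by truly monomorphic data.  Individuals with
#' a missing genotype inside a window are dropped from that window's fit.
#'
#' @param panel a [SnpGenotypes-class] of unrelated controls (QC-passed).
#' @param order Markov order k (default 1).
#' @param pseudocount added to each expected haplotype-class count after EM.
#' @param tol,maxIter EM convergence controls: stop when the largest
#'   absolute haplotype-frequency change drops below `tol`.
#' @return a [HaplotypeLDModel-class].
#' @export
fitMarkovLD <- function(panel, order = 1L, pseudocount = 0.5, tol = 1e-6,
                        maxIter = 500L) {
  k <- as.integer(order)
  if (k < 1L) stop("order must be >= 1")
  geno <- genoCodes(panel)
  map <- snpInfo(panel)
  chrIdx <- .chrSplit(map)
  pairsCache <- list()
  chrom <- list()
  ll <- numeric(0)
  for (chr in names(chrIdx)) {
    idx <- chrIdx[[chr]]
    m <- length(idx)
    g <- geno[idx, , drop = FALSE]
    w <- min(k + 1L, m)
    key <- as.character(w)
    if (is.null(pairsCache[[key]])) pairsCache[[key]] <- .patternPairs(w)
    kw <- as.character(min(k, m))
    if (is.null(pairsCache[[kw]]))
      pairsCache[[kw]] <- .patternPairs(min(k, m))

    fitWindow <- function(rows, width, pairs) {
      gw <- g[rows, , drop = FALSE]
      ok <- colSums(is.na(gw)) == 0L
      gw <- gw[, ok, drop = FALSE]
      if (ncol(gw) == 0L) {
        f <- rep(1 / 2L^width, 2L^width)
        return(list(freq = f, ll = NA_real_))
      }
      code <- as.integer(colSums(gw * 3L^(seq_len(width) - 1L)))
      patCounts <- table(code)
      freq2 <- rowMeans(gw) / 2
      fit <- .emWindow(patCounts, width, pairs, tol = tol,
                       maxIter = maxIter, init = .leInit(freq2))
      counts <- 2 * ncol(gw) * fit$freq + pseudocount
      list(freq = counts / sum(counts),
           ll = if (length(fit$logLikTrace))
                  fit$logLikTrace[length(fit$logLikTrace)] else NA_real_)
    }

    if (m <= k) {
      fit <- fitWindow(seq_len(m), m, pairsCache[[as.character(m)]])
      chrom[[chr]] <- list(snpId = map$snpId[idx],
                           alleles = cbind(map$allele1[idx],
                                           map$allele2[idx]),
                           init = fit$freq, trans = list())
      ll[chr] <- fit$ll
      next
    }
    trans <- vector("list", m - k)
    chrLL <- 0
    initDist <- NULL
    for (t in seq_len(m - k)) {
      fit <- fitWindow(t:(t + k), k + 1L, pairsCache[[key]])
      f <- fit$freq
      if (!is.na(fit$ll)) chrLL <- chrLL + fit$ll
      ## transition: context = low k bits, next allele = bit k
      ctx <- bitwAnd(seq_len(2L^(k + 1L)) - 1L, 2L^k - 1L)
      nxt <- bitwShiftR(seq_len(2L^(k + 1L)) - 1L, k)
      tm <- matrix(0, 2L^k, 2L)
      for (h in seq_along(f))
        tm[ctx[h] + 1L, nxt[h] + 1L] <- tm[ctx[h] + 1L, nxt[h] + 1L] + f[h]
      rs <- rowSums(tm)
      rs[rs == 0] <- 1
      trans[[t]] <- tm / rs
      if (t == 1L)
        initDist <- vapply(seq_len(2L^k) - 1L, function(c0)
          sum(f[ctx == c0]), numeric(1))
    }
    chrom[[chr]] <- list(snpId = map$snpId[idx],
                         alleles = cbind(map$allele1[idx], map$allele2[idx]),
                         init = initDist, trans = trans)
    ll[chr] <- chrLL
  }
  new("HaplotypeLDModel", order = k, chrom = chrom,
      nHaplotypes = 2 * ncol(geno), logLik = ll)
}

setMethod("show", "HaplotypeLDModel", function(object) {
  m <- vapply(object@chrom, function(ch) length(ch$snpId), integer(1))
  cat("HaplotypeLDModel: order ", object@order, ", ",
      length(object@chrom), " chromosome(s), ", sum(m), " SNPs",
      if (object@nHaplotypes > 0)
        paste0(", fitted from ", object@nHaplotypes, " haplotypes"),
      "\n", sep = "")
})

#' Sample founder haplotypes from a fitted LD model
#'
#' Draws allele sequences along one chromosome: the first `k` alleles from
#' the initial tuple distribution, each subsequent allele from the
#' transition distribution given the previous `k`.
#'
#' @param model a [HaplotypeLDModel-class].
#' @param chr chromosome name.
#' @param n number of haplotypes.
#' @param seed optional integer seed for reproducible draws.
#' @return integer matrix (SNPs x `n`) of allele indices 1/2.
#' @export
sampleHaplotype <- function(model, chr, n = 1L, seed = NULL) {
  .seedRNG(seed)
  ch <- model@chrom[[as.character(chr)]]
  if (is.null(ch)) stop("model has no chromosome '", chr, "'")
  k <- min(model@order, length(ch$snpId))
  m <- length(ch$snpId)
  out <- matrix(1L, m, n)
  ## initial k-tuple (bit j of the sampled index = allele at SNP j+1)
  tup <- sample.int(length(ch$init), n, replace = TRUE,
                    prob = ch$init) - 1L
  for (j in seq_len(k))
    out[j, ] <- 1L + bitwAnd(bitwShiftR(tup, j - 1L), 1L)
  if (m > k) {
    ctx <- tup
    for (t in seq_len(m - k)) {
      p2 <- ch$trans[[t]][ctx + 1L, 2L]
      a <- as.integer(stats::runif(n) < p2)       # 1 = allele 2
      out[k + t, ] <- 1L + a
      ctx <- bitwShiftR(ctx, 1L) + bitwShiftL(a, k - 1L)
    }
  }
  out
}

#' Serialize / restore a HaplotypeLDModel as versioned JSON
#'
#' @param model a [HaplotypeLDModel-class].
#' @param path file path.
#' @return `writeLDModel` returns `path` invisibly; `readLDModel` the
#'   reconstructed model.
#' @export
writeLDModel <- function(model, path) {
  obj <- list(format = "pedSGS-ldmodel", version = 1L,
              order = model@order, nHaplotypes = model@nHaplotypes,
              logLik = as.list(model@logLik),
              chrom = lapply(model@chrom, function(ch)
                list(snpId = ch$snpId,
                     allele1 = ch$alleles[, 1L], allele2 = ch$alleles[, 2L],
                     init = ch$init,
                     trans = lapply(ch$trans, function(tm)
                       as.vector(t(tm))))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLDModel
#' @export
readLDModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pedSGS-ldmodel"))
    stop("not a pedSGS LD model file: ", path)
  k <- as.integer(obj$order)
  chrom <- lapply(obj$chrom, function(ch) {
    tr <- ch$trans
    if (is.matrix(tr)) tr <- lapply(seq_len(nrow(tr)), function(i) tr[i, ])
    list(snpId = as.character(ch$snpId),
         alleles = cbind(as.character(ch$allele1),
                         as.character(ch$allele2)),
         init = as.numeric(ch$init),
         trans = lapply(tr, function(v)
           matrix(as.numeric(v), ncol = 2L, byrow = TRUE)))
  })
  ll <- unlist(obj$logLik)
  if (is.null(ll)) ll <- numeric(0)
  new("HaplotypeLDModel", order = k, chrom = chrom,
      nHaplotypes = as.numeric(obj$nHaplotypes), logLik = as.numeric(ll))
}
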