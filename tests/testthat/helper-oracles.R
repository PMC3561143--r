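# Independent brute-force oracles, kept free of the package's own
# implementation paths.

# Shortest-path meiosis count by plain breadth-first search over an
# adjacency list built directly from the individuals table.
bfsDistance <- function(individuals, from, to) {
  ids <- as.character(individuals$id)
  adj <- setNames(vector("list", length(ids)), ids)
  for (r in seq_len(nrow(individuals))) {
    id <- ids[r]
    for (p in c(individuals$father[r], individuals$mother[r])) {
      if (is.na(p) || p == "0") next
      adj[[id]] <- c(adj[[id]], p)
      adj[[p]] <- c(adj[[p]], id)
    }
  }
  dist <- setNames(rep(NA_integer_, length(ids)), ids)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == to) return(dist[[to]])
    for (nb in adj[[cur]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[[cur]] + 1L
        queue <- c(queue, nb)
      }
    }
  }
  dist[[to]]
}

# Exact conditional HWE p-value by direct enumeration of every feasible
# heterozygote count, normalizing unnormalized conditional weights.
hweEnumOracle <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  nA <- 2 * n11 + n12
  nB <- 2 * n22 + n12
  if (nA == 0 || nB == 0) return(1)
  nR <- min(nA, nB)
  hets <- seq(nR %% 2, nR, by = 2)
  logw <- sapply(hets, function(h) {
    homR <- (nR - h) / 2
    homC <- n - h - homR
    h * log(2) - lfactorial(homR) - lfactorial(h) - lfactorial(homC)
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  obs <- w[hets == n12]
  sum(w[w <= obs * (1 + 1e-12)])
}

# Run length at each locus by expanding the interval outwards, one locus at
# a time (quadratic-time scan).
runLengthOracle <- function(share) {
  n <- length(share)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (!share[i]) next
    lo <- i
    while (lo > 1 && share[lo - 1]) lo <- lo - 1
    hi <- i
    while (hi < n && share[hi + 1]) hi <- hi + 1
    out[i] <- hi - lo + 1L
  }
  out
}

# IBS sharing of a genotype-code pair, straight from the definition.
shareOracle <- function(a, b) {
  if (is.na(a)) a <- 1L
  if (is.na(b)) b <- 1L
  !((a == 0L && b == 2L) || (a == 2L && b == 0L))
}

# Pairwise run lengths for every unordered case pair, chromosome by
# chromosome, through the scan oracle.
pairRunsOracle <- function(geno, chr) {
  N <- ncol(geno)
  pairs <- utils::combn(N, 2)
  out <- matrix(0L, nrow(geno), ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    share <- vapply(seq_len(nrow(geno)), function(i)
      shareOracle(geno[i, pairs[1, p]], geno[i, pairs[2, p]]), logical(1))
    for (idx in split(seq_len(nrow(geno)), factor(chr, levels = unique(chr))))
      out[idx, p] <- runLengthOracle(share[idx])
  }
  out
}

# Per-locus sharing count by tallying pairwise-incompatible homozygotes.
sharingCountOracle <- function(geno) {
  vapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    g[is.na(g)] <- 1L
    ncol(geno) - min(sum(g == 0L), sum(g == 2L))
  }, numeric(1))
}

# Random dosage matrix with sprinkled missingness, plus a chromosome split.
randomGenoInstance <- function(nCase, nSnp, nChr = 2, missRate = 0.02) {
  geno <- matrix(sample(0:2, nCase * nSnp, replace = TRUE,
                        prob = c(0.3, 0.4, 0.3)),
                 nSnp, nCase)
  geno[runif(length(geno)) < missRate] <- NA_integer_
  sizes <- diff(unique(round(seq(0, nSnp, length.out = nChr + 1))))
  chr <- rep(paste0("chr", seq_along(sizes)), sizes)
  list(geno = geno, chr = chr)
}

# A random connected pedigree grown from a founder couple; each new
# individual is a child of a random earlier couple (one pedigree member plus
# a fresh founder spouse).  Cases are a random subset of final-generation
# members.
randomPedigreeTable <- function(nMembers = 20, nCases = 4) {
  rows <- data.frame(id = c("P1", "P2"), father = NA_character_,
                     mother = NA_character_, sex = c(1, 2),
                     status = "unknown", stringsAsFactors = FALSE)
  members <- character(0)
  lineage <- "P1"
  kid <- 0
  while (nrow(rows) < nMembers) {
    kid <- kid + 1
    parent <- sample(lineage, 1)
    if (parent == "P1") {
      mother <- "P2"
    } else {
      mother <- paste0("SP", kid)
      rows <- rbind(rows,
                    data.frame(id = mother, father = NA_character_,
                               mother = NA_character_, sex = 2,
                               status = "unknown"))
    }
    id <- paste0("C", kid)
    rows <- rbind(rows,
                  data.frame(id = id, father = parent, mother = mother,
                             sex = 1, status = "unknown"))
    lineage <- c(lineage, id)
    members <- c(members, id)
  }
  cases <- sample(members, min(nCases, length(members)))
  rows$status[rows$id %in% cases] <- "case"
  rows
}

# Uniform marker map over one or more chromosomes.
uniformMap <- function(nSnp, nChr = 1, cmSpan = 100, bpSpan = 1e8) {
  per <- rep(nSnp %/% nChr, nChr)
  per[seq_len(nSnp %% nChr)] <- per[seq_len(nSnp %% nChr)] + 1
  do.call(rbind, lapply(seq_len(nChr), function(c)
    data.frame(chr = paste0("chr", c),
               snpId = sprintf("c%d_s%04d", c, seq_len(per[c])),
               bp = round(seq(1e6, bpSpan, length.out = per[c])),
               cM = seq(0, cmSpan, length.out = per[c]),
               stringsAsFactors = FALSE)))
}
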