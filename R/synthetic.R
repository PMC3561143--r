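## Synthetic study inputs: a known-parameter LD model and genetic map, an
## unrelated control panel, and pedigree case genotypes with an embedded
## shared risk haplotype carried by a configurable subset of cases.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a dense-array pedigree study at reduced scale: 20
#' chromosomes of 100 SNPs spanning 1.5 Morgans and 100 Mb each, moderate
#' adjacent-marker LD, a 224-individual control panel, a fully penetrant
#' shared risk haplotype in the middle of chromosome 1, and low rates of
#' missingness and genotyping error.
#'
#' @param pedigree template name (see [pedigreeTemplate()]) or a
#'   [Pedigree-class].
#' @param nChrom,snpsPerChrom genome dimensions.
#' @param mapLengthMorgans,bpSpan per-chromosome genetic and physical size.
#' @param ldStrength adjacent-allele association in [0, 1]: 0 gives linkage
#'   equilibrium, 1 near-deterministic transitions.
#' @param nControls unrelated control panel size.
#' @param riskChrom,riskIndex risk-locus position (chromosome number and
#'   SNP index within it; `NULL` index means the middle SNP).
#' @param carrierFraction fraction of cases carrying the risk haplotype
#'   (1 = homogeneous, 0 = pure null).
#' @param missingRate,errorRate per-genotype missingness and symmetric
#'   genotype-error rates applied to case genotypes.
#' @param seed master seed; every downstream draw derives from it.
#' @return a list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(pedigree = "cousins5", nChrom = 20L,
                            snpsPerChrom = 100L, mapLengthMorgans = 1.5,
                            bpSpan = 1e8, ldStrength = 0.5,
                            nControls = 224L, riskChrom = 1L,
                            riskIndex = NULL, carrierFraction = 1,
                            missingRate = 0.002, errorRate = 0.001,
                            seed = 1L) {
  stopifnot(carrierFraction >= 0, carrierFraction <= 1,
            missingRate >= 0, missingRate <= 1,
            errorRate >= 0, errorRate <= 1,
            ldStrength >= 0, ldStrength <= 1,
            nChrom >= 1, snpsPerChrom >= 2)
  cfg <- list(pedigree = pedigree, nChrom = as.integer(nChrom),
              snpsPerChrom = as.integer(snpsPerChrom),
              mapLengthMorgans = mapLengthMorgans, bpSpan = bpSpan,
              ldStrength = ldStrength, nControls = as.integer(nControls),
              riskChrom = as.integer(riskChrom), riskIndex = riskIndex,
              carrierFraction = carrierFraction,
              missingRate = missingRate, errorRate = errorRate,
              seed = as.integer(seed))
  class(cfg) <- "syntheticConfig"
  cfg
}

#' Generate and write a complete synthetic study to disk
#'
#' Convenience wrapper producing every input the analysis pipeline reads:
#' the pedigree file, case and control PED/MAP pairs, a map TSV, the truth
#' record (risk locus, carriers, founder gamete, seeds) as JSON, and the
#' generating configuration as YAML.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths plus the in-memory
#'   `truth` record.
#' @export
writeSyntheticStudy <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- .configPedigree(config)
  tm <- generateTruthModel(config)
  panel <- generateControlPanel(tm$model, tm$map, config$nControls,
                                seed = deriveSeed(config$seed, 303L))
  cases <- generateCaseGenotypes(ped, tm$model, tm$map, config)
  paths <- list(
    pedFile = file.path(dir, "family.ped"),
    casesPed = file.path(dir, "cases.ped"),
    casesMap = file.path(dir, "cases.map"),
    controlsPed = file.path(dir, "controls.ped"),
    controlsMap = file.path(dir, "controls.map"),
    mapTsv = file.path(dir, "map.tsv"),
    truthJson = file.path(dir, "truth.json"),
    configYaml = file.path(dir, "config.yaml"))
  writePedigree(ped, paths$pedFile)
  writePedMap(cases$genotypes, paths$casesPed, paths$casesMap)
  writePedMap(panel, paths$controlsPed, paths$controlsMap)
  utils::write.table(tm$map, paths$mapTsv, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  jsonlite::write_json(cases$truth, paths$truthJson, auto_unbox = TRUE,
                       digits = NA)
  cfgOut <- config
  class(cfgOut) <- NULL
  if (is(cfgOut$pedigree, "Pedigree")) cfgOut$pedigree <- cfgOut$pedigree@famId
  cfgOut$riskIndex <- if (is.null(cfgOut$riskIndex)) "middle"
                      else cfgOut$riskIndex
  yaml::write_yaml(cfgOut, paths$configYaml)
  invisible(c(paths, list(truth = cases$truth)))
}

.configPedigree <- function(config) {
  if (is(config$pedigree, "Pedigree")) config$pedigree
  else pedigreeTemplate(config$pedigree)
}

#' Generate a known-parameter LD model and genetic map
#'
#' Builds an order-1 Markov truth model: per-SNP allele-1 frequencies drawn
#' uniformly on [0.1, 0.9], and transitions that interpolate between the
#' next SNP's marginal (ldStrength 0) and deterministic allele copying
#' (ldStrength 1), giving adjacent-marker correlation of about the
#' configured strength.  The map is evenly spaced in cM and bp.  Fully
#' determined by the config seed.
#'
#' @param config a [syntheticConfig()].
#' @return list with `model` ([HaplotypeLDModel-class]) and `map`
#'   (data.frame).
#' @export
generateTruthModel <- function(config) {
  .seedRNG(deriveSeed(config$seed, 101L))
  s <- config$ldStrength
  m <- config$snpsPerChrom
  chrom <- list()
  maps <- list()
  for (c in seq_len(config$nChrom)) {
    chr <- paste0("chr", c)
    q <- stats::runif(m, 0.1, 0.9)            # allele-1 frequency per SNP
    trans <- vector("list", m - 1L)
    for (t in seq_len(m - 1L)) {
      qn <- q[t + 1L]
      p11 <- qn + s * (1 - qn)                # P(next = 1 | prev = 1)
      p21 <- qn * (1 - s)                     # P(next = 1 | prev = 2)
      trans[[t]] <- rbind(c(p11, 1 - p11), c(p21, 1 - p21))
    }
    snpId <- sprintf("%s_snp%04d", chr, seq_len(m))
    chrom[[chr]] <- list(snpId = snpId,
                         alleles = cbind(rep("A", m), rep("C", m)),
                         init = c(q[1L], 1 - q[1L]), trans = trans)
    maps[[chr]] <- data.frame(
      chr = chr, snpId = snpId,
      bp = round(seq(1e6, config$bpSpan, length.out = m)),
      cM = seq(0, 100 * config$mapLengthMorgans, length.out = m),
      stringsAsFactors = FALSE)
  }
  model <- new("HaplotypeLDModel", order = 1L, chrom = chrom,
               nHaplotypes = 0, logLik = numeric(0))
  list(model = model, map = do.call(rbind, c(maps, make.row.names = FALSE)))
}

#' Generate an unrelated control panel from an LD model
#'
#' Each control is formed by pairing two independently sampled haplotypes
#' (random mating, no relatedness).
#'
#' @param model a [HaplotypeLDModel-class].
#' @param map data.frame marker map matching the model.
#' @param n number of controls (>= 2).
#' @param seed integer seed.
#' @return a [SnpGenotypes-class] with samples `CTRL0001`, ...
#' @export
generateControlPanel <- function(model, map, n, seed = NULL) {
  if (n < 2L) stop("control panel needs at least 2 individuals")
  .seedRNG(seed)
  chrIdx <- .chrSplit(map)
  geno <- matrix(NA_integer_, nrow(map), n,
                 dimnames = list(map$snpId, sprintf("CTRL%04d", seq_len(n))))
  for (chr in names(chrIdx)) {
    h <- sampleHaplotype(model, chr, n = 2L * n)
    geno[chrIdx[[chr]], ] <- (h[, seq_len(n) * 2L - 1L] - 1L) +
                             (h[, seq_len(n) * 2L] - 1L)
  }
  SnpGenotypes(geno, map)
}

## All descendants of individual `fid` (by id), including fid itself.
.descendantsOf <- function(ind, fid) {
  out <- fid
  repeat {
    more <- ind$id[ind$father %in% out | ind$mother %in% out]
    new <- setdiff(more, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

## Transmission edges (child index, side) along the descent path from the
## risk founder to each carrier case; forcing these edges to transmit the
## risk gamete at the locus makes exactly those cases carry it (up to the
## non-carrier exclusion handled by rejection).
.carrierForceEdges <- function(ped, struct, founderIdx, carrierIdx) {
  ind <- ped@individuals
  desc <- .descendantsOf(ind, ind$id[founderIdx])
  edges <- matrix(integer(0), 0L, 2L)
  for (ci in carrierIdx) {
    i <- ci
    while (i != founderIdx) {
      faId <- ind$father[i]
      if (!is.na(faId) && faId %in% desc) {
        edges <- rbind(edges, c(i, 1L))
        i <- match(faId, ind$id)
      } else if (!is.na(ind$mother[i]) && ind$mother[i] %in% desc) {
        edges <- rbind(edges, c(i, 2L))
        i <- match(ind$mother[i], ind$id)
      } else {
        stop("carrier ", ind$id[ci], " does not descend from the risk ",
             "founder")
      }
    }
  }
  unique(edges)
}

## Which founder gamete seeds the risk haplotype: gamete 1 of the first
## founder that is an ancestor of every case.
.riskGamete <- function(ped, struct) {
  ind <- ped@individuals
  for (a in seq_along(struct$founders)) {
    fIdx <- struct$founders[a]
    if (all(caseIds(ped) %in% .descendantsOf(ind, ind$id[fIdx])))
      return(list(gam = 2L * a - 1L, founderIdx = fIdx))
  }
  stop("no founder is an ancestor of every case; cannot place a shared ",
       "risk haplotype")
}

#' Generate case genotypes with an embedded shared risk haplotype
#'
#' Gene-drops the pedigree exactly as under the null, except that the
#' risk-chromosome transmissions are conditioned so the designated founder
#' gamete at the risk locus is carried identically by descent by exactly
#' the chosen carrier cases.  Transmissions on each carrier's descent path
#' are sampled conditionally (an unconditional crossover draw whose origin
#' vector is flipped when it fails to deliver the gamete at the locus — an
#' exact, measure-preserving conditioning), and drops where a non-carrier
#' also inherits the gamete are rejected.  This is distributionally
#' equivalent to plain rejection of transmissions but remains feasible at
#' large meiotic depth, and it preserves the natural recombination
#' structure, so the shared segment around the locus follows its proper
#' conditioned (length-biased) distribution.  Missingness and symmetric
#' genotype errors (hom <-> het code flips) are then applied at the
#' configured rates.
#'
#' @param ped a [Pedigree-class] (defaults to the config's).
#' @param model,map truth model and map (from [generateTruthModel()]).
#' @param config a [syntheticConfig()].
#' @param seed optional override of the config-derived seed.
#' @param maxTries rejection budget for the carrier pattern.
#' @return list with `genotypes` (a [SnpGenotypes-class] of the cases),
#'   `truth` (risk-locus coordinates, carrier ids, founder gamete, seed)
#'   and `drop` (the underlying IBD-traced [GeneDrop-class], before
#'   missingness/error).
#' @export
generateCaseGenotypes <- function(ped = NULL, model, map, config,
                                  seed = NULL, maxTries = 10000L) {
  if (is.null(ped)) ped <- .configPedigree(config)
  if (is.null(seed)) seed <- deriveSeed(config$seed, 202L)
  .seedRNG(seed)
  .checkMap(map)
  struct <- .pedStruct(ped)
  nF <- length(struct$founders)
  ids <- caseIds(ped)
  N <- length(ids)
  chrIdx <- .chrSplit(map)
  chrNames <- names(chrIdx)
  riskChr <- chrNames[config$riskChrom]
  if (is.na(riskChr)) stop("risk chromosome outside the map")
  riskIdxLocal <- if (is.null(config$riskIndex))
    ceiling(length(chrIdx[[riskChr]]) / 2) else as.integer(config$riskIndex)
  if (riskIdxLocal < 1L || riskIdxLocal > length(chrIdx[[riskChr]]))
    stop("risk locus index outside the risk chromosome")

  nCarriers <- round(config$carrierFraction * N)
  carriers <- if (nCarriers > 0L) sort(sample(ids, nCarriers)) else character(0)
  riskGam <- NA_integer_
  forceEdges <- NULL
  if (nCarriers > 0L) {
    rg <- .riskGamete(ped, struct)
    riskGam <- rg$gam
    forceEdges <- .carrierForceEdges(ped, struct, rg$founderIdx,
                                     match(carriers, struct$ids))
  }

  m <- nrow(map)
  geno <- matrix(NA_integer_, m, N, dimnames = list(map$snpId, ids))
  lab1 <- matrix(0L, m, N, dimnames = list(map$snpId, ids))
  lab2 <- lab1
  tries <- 0L
  for (chr in chrNames) {
    idx <- chrIdx[[chr]]
    cM <- map$cM[idx]
    fh <- sampleHaplotype(model, chr, n = 2L * nF)
    force <- if (chr == riskChr && nCarriers > 0L)
      list(locus = riskIdxLocal, gam = riskGam, edges = forceEdges)
    repeat {
      res <- .dropChromosome(struct, cM, force = force)
      if (is.null(force)) break
      # carriers are guaranteed by the forced transmissions; reject only
      # drops where a non-carrier also inherits the risk gamete
      hasGam <- res$L1[riskIdxLocal, ] == riskGam |
                res$L2[riskIdxLocal, ] == riskGam
      if (identical(sort(ids[hasGam]), carriers)) break
      tries <- tries + 1L
      if (tries >= maxTries)
        stop("rejection budget exhausted: carrier pattern ",
             paste(carriers, collapse = ","),
             " infeasible for this pedigree within ", maxTries, " tries")
    }
    geno[idx, ] <- .genoFromLabels(fh, res$L1, res$L2)
    lab1[idx, ] <- res$L1
    lab2[idx, ] <- res$L2
  }
  drop <- new("GeneDrop", geno = geno, lab1 = lab1, lab2 = lab2,
              map = as.data.frame(map), caseIds = ids)

  ## observation noise: missingness, then symmetric hom <-> het code flips
  obs <- geno
  if (config$missingRate > 0) {
    mask <- stats::runif(length(obs)) < config$missingRate
    obs[mask] <- NA_integer_
  }
  if (config$errorRate > 0) {
    err <- which(stats::runif(length(obs)) < config$errorRate & !is.na(obs))
    if (length(err)) {
      cur <- obs[err]
      flip <- ifelse(cur == 1L,
                     ifelse(stats::runif(length(err)) < 0.5, 0L, 2L), 1L)
      obs[err] <- flip
    }
  }
  truth <- list(riskChr = riskChr, riskIndexLocal = riskIdxLocal,
                riskIndex = chrIdx[[riskChr]][riskIdxLocal],
                riskBp = map$bp[chrIdx[[riskChr]][riskIdxLocal]],
                carriers = carriers, founderGamete = riskGam,
                seed = seed, rejections = tries)
  list(genotypes = SnpGenotypes(obs, map), truth = truth, drop = drop)
}
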