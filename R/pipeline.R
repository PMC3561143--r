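## End-to-end orchestration: QC -> LD fit -> observed scan -> gene-dropping
## null -> p-values -> regions -> (optional) genomewide thresholds, and the
## two-pedigree overlap analysis.  File-based, deterministic under a seed,
## with stage-labelled errors and a checksummed output manifest.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e),
         " (fix the inputs/config for this stage and rerun)", call. = FALSE))
}

.writeAtomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Assemble a full-scan run configuration
#'
#' @param pedFile pedigree file (see [readPedigree()]).
#' @param casesPed,casesMap PLINK text PED/MAP of the pedigree cases.
#' @param controlsPed,controlsMap PED/MAP of the unrelated control panel.
#' @param outDir output directory (created if needed).
#' @param statistics statistic tracks to scan (`"psgs"` is the primary
#'   analysis; include `"sgs"` for the all-case comparison).
#' @param alpha nominal per-locus level for region calling.
#' @param nInner inner gene-dropping replicates for the per-locus null.
#' @param thresholdGenomes outer null genomes G for genomewide thresholds
#'   (0 skips threshold estimation).
#' @param ldOrder Markov order of the LD model fit.
#' @param maskNullMissing copy the observed missingness pattern onto null
#'   replicates before computing statistics.
#' @param qcThresholds passed to [filterSnps()].
#' @param seed master seed for all randomness in the run.
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(pedFile, casesPed, casesMap, controlsPed, controlsMap,
                      outDir, statistics = c("psgs", "sgs"), alpha = 0.05,
                      nInner = 199L, thresholdGenomes = 0L, ldOrder = 1L,
                      maskNullMissing = TRUE, qcThresholds = list(),
                      seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "runConfig"
  cfg
}

#' @describeIn runConfig read a run configuration from a YAML file whose
#'   keys mirror the `runConfig()` arguments.
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(runConfig, yaml::read_yaml(path))
}

#' Run the full shared genomic segment analysis
#'
#' Executes QC, LD-model estimation from the controls, the observed pSGS
#' (and optionally SGS) scan, the gene-dropping null, per-locus empirical
#' p-values, nominal region calling and, when `thresholdGenomes > 0`,
#' empirical genomewide thresholds with per-region mu rates.  All outputs
#' (per-locus statistic TSV, regions TSV/BED per statistic, thresholds
#' JSON, manifest JSON with seeds, QC totals and file checksums) are
#' written atomically into the configured output directory.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with the in-memory results (`pedigree`,
#'   `profile`, per-statistic `pvalues` and `regions`, `thresholds`,
#'   `qcReport`, `manifest`).
#' @export
runFullScan <- function(config) {
  cfg <- config
  .stage("input", {
    paths <- c(cfg$pedFile, cfg$casesPed, cfg$casesMap, cfg$controlsPed,
               cfg$controlsMap)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  })
  ped <- .stage("pedigree", readPedigree(cfg$pedFile))
  if (!is(ped, "Pedigree"))
    stop("[stage pedigree] file holds several families; runFullScan ",
         "analyses one pedigree at a time")
  cases <- .stage("genotypes", readPedMap(cfg$casesPed, cfg$casesMap))
  controls <- .stage("genotypes", readPedMap(cfg$controlsPed,
                                             cfg$controlsMap))
  qc <- .stage("qc", {
    if (!identical(snpInfo(cases)$snpId, snpInfo(controls)$snpId))
      stop("cases and controls cover different SNP sets")
    combined <- SnpGenotypes(
      cbind(genoCodes(cases), genoCodes(controls)), snpInfo(cases),
      rbind(as.data.frame(colData(cases)), as.data.frame(colData(controls))))
    filterSnps(combined, caseIds = colnames(genoCodes(cases)),
               controlIds = colnames(genoCodes(controls)),
               thresholds = cfg$qcThresholds)
  })
  keep <- qc$report$pass
  casesQC <- cases[keep, ]
  controlsQC <- controls[keep, ]
  map <- snpInfo(casesQC)

  model <- .stage("fit-ld", fitMarkovLD(controlsQC, order = cfg$ldOrder))
  profile <- .stage("scan", sharingProfile(casesQC, ped))

  results <- list(pedigree = ped, profile = profile, qcReport = qc$report)
  files <- list()
  trackDf <- data.frame(chr = map$chr, snpId = map$snpId, bp = map$bp,
                        cM = map$cM, S = sharingCounts(profile),
                        sgs = sgsTrack(profile), psgs = psgsTrack(profile))
  for (stat in cfg$statistics) {
    store <- .stage("null", simulateNullStatistics(
      ped, model, map, cfg$nInner, statistic = stat,
      seed = deriveSeed(cfg$seed, match(stat, cfg$statistics)),
      maskFrom = if (cfg$maskNullMissing) genoCodes(casesQC)[, caseIds(ped)]))
    p <- .stage("p-values", locusPValues(profile, store))
    regions <- .stage("regions", callRegions(p, map, alpha = cfg$alpha,
                                             S = sharingCounts(profile)))
    thresholds <- NULL
    if (cfg$thresholdGenomes > 0L) {
      thresholds <- .stage("thresholds", genomewideThresholds(
        ped, model, map, G = cfg$thresholdGenomes, nInner = cfg$nInner,
        statistic = stat, alpha = cfg$alpha,
        seed = deriveSeed(cfg$seed, 1000L + match(stat, cfg$statistics)),
        innerStore = store))
      if (length(regions))
        mcols(regions)$mu <- vapply(mcols(regions)$bestP, muRate,
                                    numeric(1), pooled = thresholds$pooled,
                                    G = thresholds$G)
    }
    trackDf[[paste0("p.", stat)]] <- p
    regTsv <- file.path(cfg$outDir, paste0("regions_", stat, ".tsv"))
    regBed <- file.path(cfg$outDir, paste0("regions_", stat, ".bed"))
    .writeAtomic(function(f) exportRegions(regions, tsvPath = f), regTsv)
    .writeAtomic(function(f) exportRegions(regions, bedPath = f), regBed)
    files[[paste0("regions_", stat, ".tsv")]] <- regTsv
    files[[paste0("regions_", stat, ".bed")]] <- regBed
    if (!is.null(thresholds)) {
      thrPath <- file.path(cfg$outDir, paste0("thresholds_", stat, ".json"))
      .writeAtomic(function(f) jsonlite::write_json(
        thresholds[c("suggestive", "significant", "G", "statistic",
                     "alpha", "segmentsPerGenome")],
        f, auto_unbox = TRUE, digits = NA), thrPath)
      files[[paste0("thresholds_", stat, ".json")]] <- thrPath
    }
    results[[stat]] <- list(pvalues = p, regions = regions,
                            thresholds = thresholds)
  }
  trackPath <- file.path(cfg$outDir, "statistics.tsv")
  .writeAtomic(function(f) utils::write.table(
    trackDf, f, quote = FALSE, sep = "\t", row.names = FALSE), trackPath)
  files[["statistics.tsv"]] <- trackPath
  qcPath <- file.path(cfg$outDir, "qc_report.tsv")
  .writeAtomic(function(f) utils::write.table(
    qc$report, f, quote = FALSE, sep = "\t", row.names = FALSE), qcPath)
  files[["qc_report.tsv"]] <- qcPath

  manifest <- list(
    tool = "pedSGS",
    version = as.character(utils::packageVersion("pedSGS")),
    seed = cfg$seed, alpha = cfg$alpha, nInner = cfg$nInner,
    thresholdGenomes = cfg$thresholdGenomes, statistics = cfg$statistics,
    qcTotals = as.list(attr(qc$report, "totals")),
    nCases = nCases(ped),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  manifestPath <- file.path(cfg$outDir, "manifest.json")
  .writeAtomic(function(f) jsonlite::write_json(
    manifest, f, auto_unbox = TRUE, digits = NA), manifestPath)
  results$manifest <- manifest
  invisible(results)
}

#' Two-pedigree sharing analysis over overlapping regions
#'
#' For pedigrees with no known genealogical links, cross-pedigree sharing
#' cannot be weighted by meioses, so the unweighted paired average of
#' pairwise run lengths over the combined case set is used.  The null drops
#' both pedigrees independently from the same LD model per replicate, so
#' cross-pedigree sharing under the null arises purely from population
#' haplotype frequencies.
#'
#' @param ped1,ped2 the two [Pedigree-class] objects.
#' @param genos a [SnpGenotypes-class] holding all cases of both pedigrees.
#' @param model a [HaplotypeLDModel-class].
#' @param map data.frame marker map.
#' @param regions1,regions2 per-pedigree region calls whose pairwise
#'   intersections define the regions analysed.
#' @param nInner null replicates.
#' @param alpha nominal level (regions whose best two-pedigree p exceeds it
#'   are still reported).
#' @param seed master seed.
#' @param outPath optional TSV output path.
#' @return data.frame with one row per overlap region: chromosome, bounds,
#'   length (Mb), best two-pedigree p, and mean/min/max of the combined
#'   sharing count over the region.  Empty (with a warning) when the
#'   region sets do not overlap.
#' @export
runTwoPedigree <- function(ped1, ped2, genos, model, map, regions1,
                           regions2, nInner = 199L, alpha = 0.05,
                           seed = 1L, outPath = NULL) {
  overlap <- intersectRegions(regions1, regions2)
  if (!length(overlap)) {
    warning("no overlapping regions between the two pedigrees")
    return(data.frame())
  }
  ids <- c(caseIds(ped1), caseIds(ped2))
  geno <- genoCodes(genos)[, ids, drop = FALSE]
  track <- twoPedigreeStatistic(geno, snpInfo(genos)$chr)
  store <- simulateNullStatistics(list(ped1, ped2), model, map, nInner,
                                  statistic = "twoPed", seed = seed,
                                  maskFrom = geno)
  p <- locusPValues(track, store)
  S <- locusSharingCount(geno)
  out <- lapply(seq_along(overlap), function(i) {
    chr <- as.character(seqnames(overlap))[i]
    lo <- start(overlap)[i]; hi <- end(overlap)[i]
    loci <- which(map$chr == chr & map$bp >= lo & map$bp <= hi)
    if (!length(loci))
      return(data.frame(chr = chr, startBp = lo, endBp = hi,
                        lengthMb = round((hi - lo) / 1e6, 1),
                        bestP = NA_real_, meanSharing = NA_real_,
                        minSharing = NA_integer_, maxSharing = NA_integer_))
    sh <- regionSharingSummary(S, loci)
    data.frame(chr = chr, startBp = lo, endBp = hi,
               lengthMb = round((hi - lo) / 1e6, 1),
               bestP = min(p[loci]), meanSharing = sh[["mean"]],
               minSharing = as.integer(sh[["min"]]),
               maxSharing = as.integer(sh[["max"]]))
  })
  out <- do.call(rbind, out)
  if (!is.null(outPath))
    .writeAtomic(function(f) utils::write.table(
      out, f, quote = FALSE, sep = "\t", row.names = FALSE), outPath)
  out
}
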