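## SnpGenotypes container plus PLINK text PED/MAP reading and writing.

#' Construct a SnpGenotypes object
#'
#' @param geno numeric/integer matrix, SNPs x samples, of allele-2 dosages
#'   (0, 1, 2; `NA` = missing).  Column names are the sample ids.
#' @param map data.frame with columns `chr`, `snpId`, `bp`, `cM` and
#'   optionally `allele1`, `allele2` (default `"A"`, `"C"`).
#' @param sampleInfo optional data.frame (one row per sample) with columns
#'   such as `famId`, `father`, `mother`, `sex`, `phenotype`; carried in
#'   `colData` and used when writing PED files.
#' @return a [SnpGenotypes-class].
#' @export
SnpGenotypes <- function(geno, map, sampleInfo = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (is.null(map$allele1)) map$allele1 <- "A"
  if (is.null(map$allele2)) map$allele2 <- "C"
  .checkMap(map, requireAlleles = TRUE)
  if (nrow(map) != nrow(geno))
    stop("genotype matrix and marker map disagree on SNP count")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("S", seq_len(ncol(geno)))
  rownames(geno) <- map$snpId
  if (is.null(sampleInfo)) {
    sampleInfo <- data.frame(famId = colnames(geno), father = "0",
                             mother = "0", sex = 0L, phenotype = 0L,
                             row.names = colnames(geno),
                             stringsAsFactors = FALSE)
  } else {
    sampleInfo <- as.data.frame(sampleInfo, stringsAsFactors = FALSE)
    rownames(sampleInfo) <- colnames(geno)
  }
  se <- SummarizedExperiment(assays = list(geno = geno),
                             rowData = map, colData = sampleInfo)
  new("SnpGenotypes", se)
}

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "SnpGenotypes", function(x)
  as.data.frame(rowData(x), stringsAsFactors = FALSE))

#' @rdname snpInfo
#' @export
setMethod("genoCodes", "SnpGenotypes", function(x) assay(x, "geno"))

setMethod("show", "SnpGenotypes", function(object) {
  map <- snpInfo(object)
  g <- genoCodes(object)
  cat("SnpGenotypes: ", nrow(g), " SNPs x ", ncol(g), " samples on ",
      length(unique(map$chr)), " chromosome(s); ",
      sprintf("%.2f%%", 100 * mean(is.na(g))), " missing\n", sep = "")
})

#' Read a PLINK text PED/MAP pair
#'
#' MAP columns: chromosome, SNP id, genetic position (cM), physical position
#' (bp).  PED rows: family id, individual id, father, mother, sex, phenotype,
#' then two allele columns per SNP.  Allele 1 is the lexicographically
#' smaller of the two labels observed at a SNP; `0` denotes a missing allele
#' and any genotype containing it is read as missing.
#'
#' @param pedPath,mapPath file paths.
#' @return a [SnpGenotypes-class].
#' @export
readPedMap <- function(pedPath, mapPath) {
  for (p in c(pedPath, mapPath))
    if (!file.exists(p)) stop("file not found: ", p)
  map <- utils::read.table(mapPath, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chr", "snpId", "cM", "bp"))
  map <- map[, c("chr", "snpId", "bp", "cM")]
  map$chr <- as.character(map$chr)
  .checkMap(map)
  m <- nrow(map)

  ped <- data.table::fread(pedPath, header = FALSE, data.table = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6L + 2L * m)
    stop("PED row length (", ncol(ped), " fields) does not match map (",
         m, " SNPs need ", 6L + 2L * m, ")")
  sampleInfo <- data.frame(famId = ped[[1]], father = ped[[3]],
                           mother = ped[[4]], sex = as.integer(ped[[5]]),
                           phenotype = as.integer(ped[[6]]),
                           stringsAsFactors = FALSE)
  ids <- make.unique(ped[[2]])

  n <- nrow(ped)
  geno <- matrix(NA_integer_, m, n, dimnames = list(map$snpId, ids))
  a1 <- a2 <- character(m)
  for (s in seq_len(m)) {
    x <- as.character(ped[[5L + 2L * s]])
    y <- as.character(ped[[6L + 2L * s]])
    missing <- x == "0" | y == "0"
    obs <- sort(unique(c(x[!missing], y[!missing])))
    if (length(obs) > 2L)
      stop("SNP ", map$snpId[s], " has more than two alleles: ",
           paste(obs, collapse = ", "))
    if (length(obs) == 0L) obs <- c("A", "C")            # fully missing SNP
    if (length(obs) == 1L) obs <- c(obs, paste0(obs, "x"))  # monomorphic
    a1[s] <- obs[1]; a2[s] <- obs[2]
    g <- (x == obs[2]) + (y == obs[2])
    g[missing] <- NA_integer_
    geno[s, ] <- as.integer(g)
  }
  map$allele1 <- a1
  map$allele2 <- a2
  SnpGenotypes(geno, map, sampleInfo)
}

#' Write a SnpGenotypes object as a PLINK text PED/MAP pair
#'
#' Inverse of [readPedMap()]: space-delimited, missing genotypes written as
#' `0 0`, heterozygotes as `allele1 allele2`.
#'
#' @param x a [SnpGenotypes-class].
#' @param pedPath,mapPath output file paths.
#' @return invisibly, the two paths.
#' @export
writePedMap <- function(x, pedPath, mapPath) {
  map <- snpInfo(x)
  geno <- genoCodes(x)
  info <- as.data.frame(colData(x), stringsAsFactors = FALSE)
  utils::write.table(
    data.frame(map$chr, map$snpId, map$cM, map$bp),
    mapPath, quote = FALSE, sep = " ",
    row.names = FALSE, col.names = FALSE)

  n <- ncol(geno)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- geno[, i]
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2L, map$allele2, map$allele1))
    x2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, map$allele2, map$allele1))
    lines[i] <- paste(c(info$famId[i], colnames(geno)[i], info$father[i],
                        info$mother[i], info$sex[i], info$phenotype[i],
                        as.vector(rbind(x1, x2))), collapse = " ")
  }
  writeLines(lines, pedPath)
  invisible(c(ped = pedPath, map = mapPath))
}
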