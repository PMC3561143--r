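## Pedigree representation, validation and meiotic-distance queries.

.validatePedigree <- function(individuals, caseIds) {
  req <- c("id", "father", "mother", "sex", "status")
  miss <- setdiff(req, names(individuals))
  if (length(miss))
    stop("individuals table lacks column(s): ", paste(miss, collapse = ", "))
  ids <- as.character(individuals$id)
  if (anyDuplicated(ids))
    stop("duplicated individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fa <- as.character(individuals$father)
  mo <- as.character(individuals$mother)
  oneParent <- xor(is.na(fa), is.na(mo))
  if (any(oneParent))
    stop("individual(s) with exactly one recorded parent: ",
         paste(ids[oneParent], collapse = ", "),
         " (gene-dropping requires both parents or neither)")
  ref <- c(fa[!is.na(fa)], mo[!is.na(mo)])
  missingParent <- setdiff(unique(ref), ids)
  if (length(missingParent))
    stop("missing parent record(s): ", paste(missingParent, collapse = ", "))

  ## Cycle check (covers self-ancestry): Kahn's algorithm on parent -> child
  ## edges; leftovers after repeated founder stripping imply a cycle.
  remaining <- ids
  faq <- stats::setNames(fa, ids)
  moq <- stats::setNames(mo, ids)
  repeat {
    free <- remaining[
      (!(faq[remaining] %in% remaining) | is.na(faq[remaining])) &
      (!(moq[remaining] %in% remaining) | is.na(moq[remaining]))]
    if (!length(free)) break
    remaining <- setdiff(remaining, free)
    if (!length(remaining)) break
  }
  if (length(remaining))
    stop("cycle detected in the ancestry graph (individuals: ",
         paste(remaining, collapse = ", "), ")")

  if (!all(caseIds %in% ids))
    stop("case id(s) absent from pedigree: ",
         paste(setdiff(caseIds, ids), collapse = ", "))
  if (length(caseIds) < 2L)
    stop("fewer than 2 cases: shared segment analysis needs N >= 2")

  ## Every pair of cases must be connected through the pedigree graph.
  g <- .pedGraphFrom(ids, fa, mo)
  comp <- igraph::components(g)$membership[caseIds]
  if (length(unique(comp)) > 1L)
    stop("cases are not all connected through the pedigree")
  invisible(TRUE)
}

.pedGraphFrom <- function(ids, fa, mo) {
  edges <- rbind(
    data.frame(from = ids[!is.na(fa)], to = fa[!is.na(fa)]),
    data.frame(from = ids[!is.na(mo)], to = mo[!is.na(mo)]))
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids))
}

.pedGraph <- function(ped) {
  ind <- ped@individuals
  .pedGraphFrom(as.character(ind$id),
                as.character(ind$father),
                as.character(ind$mother))
}

#' Construct a Pedigree
#'
#' @param individuals data.frame with columns `id`, `father`, `mother`
#'   (`NA` or `"0"` for absent), `sex` (1/2/0) and `status` (`"case"` /
#'   `"unknown"`, or the file coding 2 = case, 0/1 = unknown).
#' @param caseIds case identifiers in analysis order; defaults to the
#'   individuals flagged as cases, in table order.
#' @param famId family label.
#' @return a validated [Pedigree-class].
#' @export
Pedigree <- function(individuals, caseIds = NULL, famId = "PED") {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  individuals$id     <- as.character(individuals$id)
  individuals$father <- as.character(individuals$father)
  individuals$mother <- as.character(individuals$mother)
  individuals$father[individuals$father %in% "0"] <- NA_character_
  individuals$mother[individuals$mother %in% "0"] <- NA_character_
  if (!is.character(individuals$status))
    individuals$status <- ifelse(individuals$status == 2, "case", "unknown")
  individuals$status <- ifelse(individuals$status == "case", "case", "unknown")
  if (is.null(caseIds))
    caseIds <- individuals$id[individuals$status == "case"]
  .validatePedigree(individuals, caseIds)
  new("Pedigree", individuals = individuals, caseIds = as.character(caseIds),
      famId = as.character(famId))
}

#' Read pedigrees from a pre-makeped LINKAGE/FAM style file
#'
#' Whitespace-delimited columns: family id, individual id, father id, mother
#' id, sex (1 = male, 2 = female, 0 = unknown), status (2 = case, 0/1 =
#' unknown).  `"0"` denotes an absent parent.  One pedigree per family id.
#'
#' @param path file path.
#' @return a [Pedigree-class] if the file holds one family, otherwise a named
#'   list of them.
#' @export
readPedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("famId", "id", "father", "mother",
                                         "sex", "status"))
  peds <- lapply(split(tab, factor(tab$famId, levels = unique(tab$famId))),
                 function(fam) {
    Pedigree(fam[, c("id", "father", "mother", "sex", "status")],
             famId = as.character(fam$famId[1]))
  })
  if (length(peds) == 1L) peds[[1]] else peds
}

#' Write a pedigree back to the LINKAGE/FAM style file format
#'
#' @param ped a [Pedigree-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writePedigree <- function(ped, path) {
  ind <- ped@individuals
  writeLines(paste(ped@famId, ind$id,
                   ifelse(is.na(ind$father), "0", ind$father),
                   ifelse(is.na(ind$mother), "0", ind$mother),
                   ind$sex, ifelse(ind$status == "case", 2L, 0L)), path)
  invisible(path)
}

#' @rdname Pedigree-class
#' @export
setMethod("caseIds", "Pedigree", function(x) x@caseIds)

#' @rdname Pedigree-class
#' @export
setMethod("nCases", "Pedigree", function(x) length(x@caseIds))

#' @rdname Pedigree-class
#' @export
setMethod("founderIds", "Pedigree", function(x) {
  ind <- x@individuals
  ind$id[is.na(ind$father) & is.na(ind$mother)]
})

#' @describeIn meioticDistance shortest-path meiosis count via the
#'   undirected parent-child graph.
#' @export
setMethod("meioticDistance", "Pedigree", function(ped, j, k) {
  j <- as.character(j); k <- as.character(k)
  ids <- ped@individuals$id
  if (!all(c(j, k) %in% ids))
    stop("unknown individual id(s): ",
         paste(setdiff(c(j, k), ids), collapse = ", "))
  if (j == k) stop("meiotic distance requires two distinct individuals")
  d <- igraph::distances(.pedGraph(ped), v = j, to = k)[1, 1]
  if (!is.finite(d))
    stop("individuals ", j, " and ", k, " are not connected in the pedigree")
  as.integer(d)
})

#' @describeIn pairWeights meiosis counts for all case pairs of a pedigree.
#' @export
setMethod("pairWeights", "Pedigree", function(ped) {
  ids <- caseIds(ped)
  d <- igraph::distances(.pedGraph(ped), v = ids, to = ids)
  if (any(!is.finite(d)))
    stop("some case pairs are not connected through the pedigree")
  storage.mode(d) <- "integer"
  dimnames(d) <- list(ids, ids)
  d
})

#' @describeIn pairWeights long form: one row per unordered case pair with
#'   its meiosis count `d`, in the pair order used throughout the package.
#' @export
setMethod("pairTable", "Pedigree", function(ped) {
  ids <- caseIds(ped)
  w <- pairWeights(ped)
  pr <- .pairIndex(length(ids))
  data.frame(j = ids[pr[1, ]], k = ids[pr[2, ]],
             d = w[cbind(pr[1, ], pr[2, ])],
             stringsAsFactors = FALSE)
})

setMethod("show", "Pedigree", function(object) {
  pt <- pairTable(object)
  cat("Pedigree '", object@famId, "': ", nrow(object@individuals),
      " individuals, ", nCases(object), " cases (",
      length(founderIds(object)), " founders)\n", sep = "")
  cat("  case pairs: ", nrow(pt), "; meioses per pair ", min(pt$d), "-",
      max(pt$d), "; total over pairs ", sum(pt$d), "\n", sep = "")
})
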