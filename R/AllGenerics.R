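#' @rdname Pedigree-class
#' @param x,object a package object.
#' @export
setGeneric("caseIds", function(x) standardGeneric("caseIds"))

#' @rdname Pedigree-class
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname Pedigree-class
#' @export
setGeneric("founderIds", function(x) standardGeneric("founderIds"))

#' Meiotic distance between two cases
#'
#' Number of meioses separating two genotyped cases: the length of the
#' shortest path between them in the undirected parent-child graph, each
#' parent-child transmission counting one meiosis.  Full siblings are 2
#' meioses apart, first cousins 4.
#'
#' @param ped a [Pedigree-class].
#' @param j,k case identifiers, `j != k`.
#' @return single positive integer.
#' @examples
#' ped <- pedigreeTemplate("nuclear")
#' meioticDistance(ped, caseIds(ped)[1], caseIds(ped)[2])  # siblings: 2
#' @export
setGeneric("meioticDistance", function(ped, j, k) standardGeneric("meioticDistance"))

#' Pairwise meiosis-count weight matrix for the cases of a pedigree
#'
#' @param ped a [Pedigree-class].
#' @return symmetric integer matrix over the case identifiers; `d[j, k]` is
#'   the meiotic distance between cases j and k (diagonal 0).
#' @seealso [pairTable()] for the long (j, k, d) form used as pSGS weights.
#' @export
setGeneric("pairWeights", function(ped) standardGeneric("pairWeights"))

#' @rdname pairWeights
#' @export
setGeneric("pairTable", function(ped) standardGeneric("pairTable"))

#' Marker map and genotype code accessors
#'
#' `snpInfo()` returns the marker map (chr, snpId, bp, cM, alleles) as a
#' data.frame; `genoCodes()` the allele-2 dosage matrix (SNPs x samples,
#' `NA` = missing).
#'
#' @param x a [SnpGenotypes-class].
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname snpInfo
#' @export
setGeneric("genoCodes", function(x) standardGeneric("genoCodes"))

#' @rdname GeneDrop-class
#' @export
setGeneric("caseGenotypes", function(x) standardGeneric("caseGenotypes"))

#' @rdname GeneDrop-class
#' @export
setGeneric("ibdLabels", function(x) standardGeneric("ibdLabels"))

#' @rdname SharingProfile-class
#' @export
setGeneric("sharingCounts", function(x) standardGeneric("sharingCounts"))

#' @rdname SharingProfile-class
#' @export
setGeneric("psgsTrack", function(x) standardGeneric("psgsTrack"))

#' @rdname SharingProfile-class
#' @export
setGeneric("sgsTrack", function(x) standardGeneric("sgsTrack"))

#' @rdname SharingProfile-class
#' @export
setGeneric("pairRuns", function(x) standardGeneric("pairRuns"))

#' @rdname NullStatisticStore-class
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))
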