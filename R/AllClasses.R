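## S4 class definitions.  Validity logic that needs non-trivial computation
## (cycle detection, map ordering) lives next to the constructors.

#' Pedigree of related individuals with flagged, genotyped cases
#'
#' An extended pedigree: a directed ancestry graph over individuals, a subset
#' of whom are disease cases.  Only cases are genotyped; all other individuals
#' are "unknown" placeholders that define the transmission structure.  Both
#' parents must be recorded or neither (founder), the ancestry graph must be
#' acyclic, and every pair of cases must be connected through the pedigree.
#'
#' @slot individuals data.frame with columns `id`, `father`, `mother`
#'   (`NA` for founders), `sex` (1 male / 2 female / 0 unknown) and
#'   `status` (`"case"` or `"unknown"`).
#' @slot caseIds character, the genotyped case identifiers in input order
#'   (length N >= 2).
#' @slot famId single character family label.
#'
#' @seealso [readPedigree()], [pedigreeTemplate()], [meioticDistance()],
#'   [pairWeights()]
#' @export
setClass("Pedigree",
  representation(individuals = "data.frame",
                 caseIds     = "character",
                 famId       = "character"))

#' SNP genotypes with marker metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] specialization holding
#' biallelic SNP genotypes as an allele-2 dosage matrix (SNPs x samples;
#' 0 = hom allele-1 "11", 1 = het "12", 2 = hom allele-2 "22", `NA` =
#' missing).  Row metadata carries the marker map: `chr`, `snpId`, `bp`
#' (1-based physical position), `cM` (sex-averaged map position) and the
#' two allele labels (`allele1` lexicographically smaller).  Within each
#' chromosome `bp` is strictly increasing and `cM` non-decreasing, and
#' chromosomes occupy contiguous row blocks.
#'
#' @seealso [SnpGenotypes()], [readPedMap()], [snpInfo()], [genoCodes()]
#' @export
setClass("SnpGenotypes", contains = "SummarizedExperiment")

#' Markov haplotype model of linkage disequilibrium
#'
#' An order-k Markov chain over alleles along each chromosome, estimated from
#' unrelated control genotypes and used to sample founder haplotypes for the
#' gene-dropping null.  This captures the serial (adjacent-marker) LD that
#' inflates IBS run lengths under the null.
#'
#' @slot order integer Markov order k (default 1).
#' @slot chrom named list, one entry per chromosome, each a list with
#'   `snpId`, `alleles` (m x 2 character), `init` (probability vector over
#'   the 2^min(k, m) allele tuples at the chromosome start) and `trans`
#'   (list of 2^k x 2 transition matrices, one per step).
#' @slot nHaplotypes numeric, number of haplotypes (2 x individuals) the
#'   model was fitted from (0 for constructed models).
#' @slot logLik numeric, final composite log-likelihood per chromosome
#'   (NA for constructed models).
#'
#' @seealso [fitMarkovLD()], [sampleHaplotype()], [writeLDModel()]
#' @export
setClass("HaplotypeLDModel",
  representation(order       = "integer",
                 chrom       = "list",
                 nHaplotypes = "numeric",
                 logLik      = "numeric"))

#' Result of one gene-dropping replicate
#'
#' Genotypes (and, optionally, founder-gamete identity-by-descent labels) for
#' the pedigree cases after segregating LD-model founder haplotypes through
#' the pedigree with genetic-map recombination.
#'
#' @slot geno matrix (SNPs x cases) of allele-2 dosages, or `NULL` when only
#'   IBD bookkeeping was requested.
#' @slot lab1,lab2 integer matrices (SNPs x cases) giving the founder-gamete
#'   label of the paternally / maternally transmitted allele, or `NULL` when
#'   tracing was off.  Founder f contributes gametes 2f-1 and 2f.
#' @slot map data.frame marker map (chr, snpId, bp, cM).
#' @slot caseIds character case identifiers (column order of the matrices).
#'
#' @seealso [dropGenome()], [ibdSegments()]
#' @export
setClass("GeneDrop",
  representation(geno    = "ANY",
                 lab1    = "ANY",
                 lab2    = "ANY",
                 map     = "data.frame",
                 caseIds = "character"))

#' Per-locus sharing profile of a pedigree's cases
#'
#' Holds, for every SNP, the IBS sharing count S_i, the pairwise run lengths
#' R_i^jk(2) for all case pairs, and the derived statistic tracks: the
#' all-case SGS run length R_i(N) and the meiosis-weighted pairwise pSGS
#' statistic.
#'
#' @slot map data.frame marker map (chr, snpId, bp, cM).
#' @slot S integer vector, cases sharing at each locus.
#' @slot pairRuns integer matrix (SNPs x pairs) of pairwise run lengths.
#' @slot pairs data.frame with columns `j`, `k`, `d` (meiosis count) for
#'   each unordered case pair, in column order of `pairRuns`.
#' @slot psgs numeric pSGS track (weighted mean of pairwise run lengths).
#' @slot sgs integer SGS track (all-case run length).
#' @slot caseIds character case identifiers.
#'
#' @seealso [sharingProfile()], [psgsStatistic()], [sgsStatistic()]
#' @export
setClass("SharingProfile",
  representation(map      = "data.frame",
                 S        = "integer",
                 pairRuns = "matrix",
                 pairs    = "data.frame",
                 psgs     = "numeric",
                 sgs      = "integer",
                 caseIds  = "character"))

#' Store of null statistic values from gene-dropping replicates
#'
#' Per-locus collections of a sharing statistic computed on gene-dropped null
#' genotype configurations, used to convert observed statistics to empirical
#' p-values.
#'
#' @slot values numeric matrix (replicates x SNPs) of null statistic values.
#' @slot statistic one of `"psgs"`, `"sgs"`, `"twoPed"`.
#' @slot map data.frame marker map the values are aligned to.
#' @slot seed the seed the replicates were generated from (or `NULL`).
#'
#' @seealso [simulateNullStatistics()], [locusPValues()]
#' @export
setClass("NullStatisticStore",
  representation(values    = "matrix",
                 statistic = "character",
                 map       = "data.frame",
                 seed      = "ANY"))

setValidity("NullStatisticStore", function(object) {
  if (nrow(object@values) < 1L)
    return("null store needs at least one replicate")
  if (!object@statistic %in% c("psgs", "sgs", "twoPed"))
    return("statistic must be one of 'psgs', 'sgs', 'twoPed'")
  if (ncol(object@values) != nrow(object@map))
    return("values and map disagree on locus count")
  if (any(object@values < 0, na.rm = TRUE))
    return("null statistic values must be non-negative")
  TRUE
})
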