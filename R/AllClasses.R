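#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' MutationSet: multi-sample somatic mutations with read counts
#'
#' An extension of \linkS4class{RangedSummarizedExperiment} holding one row per
#' somatic mutation and one column per tumor sample from the same patient.
#' The \code{"alt"} assay holds variant read counts X and the \code{"depth"}
#' assay total depths n; \code{rowRanges} carries the genomic position
#' (1-based, VCF convention) and \code{rowData} the ref/alt alleles, mutation
#' class (\code{substitution}, \code{insertion}, \code{deletion}, \code{SV}),
#' and optional gene, consequence and trinucleotide channel annotations.
#' Sample purity lives in \code{colData(x)$purity}. Downstream steps add
#' assays \code{"totalCN"}, \code{"multiplicity"} and \code{"ccf"}.
#'
#' A depth of 0 means the site was not typed in that sample; it is distinct
#' from typed-but-absent, which requires the binomial presence test.
#'
#' @seealso [MutationSet()], [readMutationTable()], [computeCCF()]
#' @export
setClass("MutationSet", contains = "RangedSummarizedExperiment")

setValidity("MutationSet", function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("alt", "depth") %in% an))
        msg <- c(msg, "assays 'alt' and 'depth' are required")
    else {
        X <- SummarizedExperiment::assay(object, "alt")
        n <- SummarizedExperiment::assay(object, "depth")
        if (any(X < 0, na.rm = TRUE) || any(n < 0, na.rm = TRUE))
            msg <- c(msg, "read counts must be non-negative")
        bad <- which(X > n)
        if (length(bad))
            msg <- c(msg, sprintf("variant reads exceed depth at %d entr%s (first row %d)",
                                  length(bad), if (length(bad) == 1L) "y" else "ies",
                                  (bad[1L] - 1L) %% nrow(X) + 1L))
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("ref", "alt", "class")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, paste("rowData must contain", paste(need, collapse = ", ")))
    else if (!all(rd$class %in% c("substitution", "insertion", "deletion", "SV")))
        msg <- c(msg, "unknown mutation class")
    if (!"purity" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain 'purity'")
    else {
        rho <- SummarizedExperiment::colData(object)$purity
        if (any(rho <= 0 | rho > 1)) msg <- c(msg, "purity must lie in (0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' SignatureCatalog: 96-channel mutational signature probabilities
#'
#' Holds a 96 x K matrix of channel probabilities, rows fixed to the COSMIC
#' channel order (see [channelNames()]), one column per signature. Every
#' column sums to 1.
#'
#' @seealso [readSignatureCatalog()], [syntheticSignatureCatalog()]
#' @export
setClass("SignatureCatalog", representation(probs = "matrix"))

setValidity("SignatureCatalog", function(object) {
    p <- object@probs
    msg <- NULL
    if (nrow(p) != 96L) msg <- c(msg, "catalogue must have 96 channels")
    if (any(p < 0)) msg <- c(msg, "probabilities must be non-negative")
    cs <- colSums(p)
    if (length(cs) && any(abs(cs - 1) > 1e-3))
        msg <- c(msg, sprintf("column '%s' sums to %.4f, not 1",
                              colnames(p)[which.max(abs(cs - 1))],
                              cs[which.max(abs(cs - 1))]))
    if (!identical(rownames(p), channelNames()))
        msg <- c(msg, "rows must be the canonical 96 channels in COSMIC order")
    if (is.null(msg)) TRUE else msg
})

#' ClusterSet: posterior mutation clusters across related samples
#'
#' Result of [dpCluster()]. Each cluster carries a per-sample cancer cell
#' fraction (posterior median) with a 95\% credible interval, a size, and
#' the ids of its member mutations. \code{assignments} maps every clustered
#' mutation to a cluster; \code{memberships} holds posterior membership
#' probabilities used for branch assignment.
#'
#' @seealso [dpCluster()], [buildTree()]
#' @export
setClass("ClusterSet", representation(
    ccf = "matrix",        # clusters x samples, posterior median CCF
    ccfLower = "matrix",   # 2.5% bound
    ccfUpper = "matrix",   # 97.5% bound
    sizes = "integer",
    assignments = "integer",   # per mutation, index into clusters
    memberships = "matrix",    # mutations x clusters posterior probabilities
    mutationIds = "character",
    merged = "logical",        # cluster absorbed a sub-threshold cluster?
    diagnostics = "list"))

setValidity("ClusterSet", function(object) {
    msg <- NULL
    if (length(object@sizes) != nrow(object@ccf))
        msg <- c(msg, "one size per cluster required")
    if (sum(object@sizes) != sum(!is.na(object@assignments)))
        msg <- c(msg, "cluster sizes must sum to the number of clustered mutations")
    if (any(object@ccf < 0 | object@ccf > 1.2))
        msg <- c(msg, "cluster CCFs must lie in [0, 1.2]")
    if (length(object@mutationIds) != length(object@assignments))
        msg <- c(msg, "one assignment per mutation required")
    if (is.null(msg)) TRUE else msg
})

#' PhyloTree: rooted tree of mutation clusters
#'
#' Clusters ordered by the pigeonhole principle: a cluster is ancestral to
#' another only if its CCF dominates in every sample, and sibling CCFs may
#' not sum above their parent's in any sample (within tolerance `tol`).
#' `parent` uses NA for the trunk. `alternatives` holds any other parent
#' vectors consistent with the constraints, ranked after the primary
#' (deepest-nesting) solution stored in the object itself.
#'
#' @seealso [buildTree()], [exportNewick()]
#' @export
setClass("PhyloTree", representation(
    clusterIds = "character",
    parent = "integer",
    ccf = "matrix",
    branchMutations = "list",   # per cluster, character vector of mutation ids
    branchCounts = "matrix",    # per cluster: substitution/insertion/deletion/SV
    alternatives = "list",
    tol = "numeric"))

setValidity("PhyloTree", function(object) {
    msg <- NULL
    k <- length(object@clusterIds)
    if (sum(is.na(object@parent)) != 1L)
        msg <- c(msg, "exactly one root (trunk) required")
    if (length(object@parent) != k || nrow(object@ccf) != k)
        msg <- c(msg, "parent and ccf must have one entry per cluster")
    tol <- object@tol
    for (i in seq_len(k)) {
        p <- object@parent[i]
        if (is.na(p)) next
        if (any(object@ccf[i, ] > object@ccf[p, ] + tol)) {
            msg <- c(msg, sprintf("cluster %s exceeds its parent's CCF",
                                  object@clusterIds[i]))
            break
        }
    }
    for (p in seq_len(k)) {
        kids <- which(!is.na(object@parent) & object@parent == p)
        if (length(kids) >= 2L &&
            any(colSums(object@ccf[kids, , drop = FALSE]) >
                object@ccf[p, ] + tol)) {
            msg <- c(msg, sprintf("children of %s violate the pigeonhole sum",
                                  object@clusterIds[p]))
            break
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' WGDTiming: relative molecular time of whole-genome duplication
#'
#' Mixture proportions over early-clonal (pre-duplication, multiplicity 2),
#' late-clonal (post-duplication, multiplicity 1) and subclonal states,
#' the derived relative time t = 2*pi_e / (2*pi_e + pi_l), and a percentile
#' bootstrap confidence interval.
#'
#' @seealso [timeWGD()], [wgdEM()], [wgdTime()]
#' @export
setClass("WGDTiming", representation(
    t = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    pi = "numeric",
    logLik = "numeric",
    nMutations = "integer",
    bootstrapT = "numeric"))

setValidity("WGDTiming", function(object) {
    msg <- NULL
    if (length(object@t) == 1 && length(object@ciLow) == 1 &&
        !is.na(object@ciLow) &&
        (object@ciLow > object@t || object@ciHigh < object@t))
        msg <- c(msg, "confidence interval must contain the point estimate")
    if (abs(sum(object@pi) - 1) > 1e-6)
        msg <- c(msg, "mixture proportions must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' ExposureSolution: selected signature subset with exposures
#'
#' The signature subset (at most 7 signatures) chosen by exhaustive model
#' selection, the fitted exposure counts, and the Pearson correlation r
#' between the observed and reconstructed 96-channel spectrum. `audit`
#' summarises why competing solutions were discarded.
#'
#' @seealso [selectModel()], [fitExposures()], [branchSignatures()]
#' @export
setClass("ExposureSolution", representation(
    signatures = "character",
    exposures = "numeric",
    r = "numeric",
    total = "numeric",
    audit = "list"))

setValidity("ExposureSolution", function(object) {
    msg <- NULL
    if (length(object@signatures) > 7L)
        msg <- c(msg, "at most 7 signatures per solution")
    if (any(object@exposures < -1e-9))
        msg <- c(msg, "exposures must be non-negative")
    if (length(object@exposures) != length(object@signatures))
        msg <- c(msg, "one exposure per signature")
    if (is.null(msg)) TRUE else msg
})

#' SyntheticPatient: simulated multi-sample patient with ground truth
#'
#' Output of [simulatePatient()]: a [MutationSet], per-sample copy-number
#' segments (a \linkS4class{GRanges} with a `sample` column), and a truth
#' table recording each mutation's branch, per-sample CCF, multiplicity and
#' generating signature.
#'
#' @export
setClass("SyntheticPatient", representation(
    mutations = "MutationSet",
    segments = "GRanges",
    truth = "data.frame",
    config = "list"))

setValidity("SyntheticPatient", function(object) {
    msg <- NULL
    if (nrow(object@truth) != nrow(object@mutations))
        msg <- c(msg, "exactly one truth branch per mutation required")
    if (!all(c("mutation_id", "branch_id", "multiplicity", "signature_id") %in%
             colnames(object@truth)))
        msg <- c(msg, "truth table is missing required columns")
    if (is.null(msg)) TRUE else msg
})
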