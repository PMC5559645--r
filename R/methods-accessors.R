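#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("altCounts", "MutationSet", function(x, ...)
    SummarizedExperiment::assay(x, "alt"))

#' @rdname accessors
#' @export
setMethod("depths", "MutationSet", function(x, ...)
    SummarizedExperiment::assay(x, "depth"))

#' @rdname accessors
#' @export
setMethod("purity", "MutationSet", function(x, ...) {
    rho <- SummarizedExperiment::colData(x)$purity
    names(rho) <- colnames(x)
    rho
})

#' @rdname accessors
#' @export
setMethod("vaf", "MutationSet", function(x, ...) {
    X <- altCounts(x); n <- depths(x)
    v <- X / n
    v[n == 0] <- NA_real_
    v
})

#' @rdname accessors
#' @export
setMethod("ccf", "MutationSet", function(x, ...) {
    if (!"ccf" %in% SummarizedExperiment::assayNames(x))
        stopf("CCF assay not present; run computeCCF() first")
    SummarizedExperiment::assay(x, "ccf")
})

#' @rdname accessors
#' @export
setMethod("ccf", "ClusterSet", function(x, ...) x@ccf)

#' @rdname accessors
#' @export
setMethod("ccf", "PhyloTree", function(x, ...) x@ccf)

#' @rdname accessors
#' @export
setMethod("clusterSizes", "ClusterSet", function(x, ...) x@sizes)

#' @rdname accessors
#' @export
setMethod("assignments", "ClusterSet", function(x, ...) {
    a <- x@assignments
    names(a) <- x@mutationIds
    a
})

#' @rdname accessors
#' @export
setMethod("memberships", "ClusterSet", function(x, ...) x@memberships)

#' @rdname accessors
#' @export
setMethod("signatureNames", "SignatureCatalog", function(x, ...)
    colnames(x@probs))

#' @rdname accessors
#' @export
setMethod("probs", "SignatureCatalog", function(x, ...) x@probs)

#' @rdname accessors
#' @export
setMethod("exposures", "ExposureSolution", function(x, ...) {
    e <- x@exposures
    names(e) <- x@signatures
    e
})

#' @rdname accessors
#' @export
setMethod("signatureNames", "ExposureSolution", function(x, ...) x@signatures)

#' @rdname accessors
#' @export
setMethod("reconstructionR", "ExposureSolution", function(x, ...) x@r)

#' @rdname accessors
#' @export
setMethod("wgdTimeEstimate", "WGDTiming", function(x, ...) x@t)

#' @rdname accessors
#' @export
setMethod("wgdCI", "WGDTiming", function(x, ...)
    c(lower = x@ciLow, upper = x@ciHigh))

#' @rdname accessors
#' @export
setMethod("mixtureProportions", "WGDTiming", function(x, ...) x@pi)

#' @rdname accessors
#' @export
setMethod("parentIndex", "PhyloTree", function(x, ...) {
    p <- x@parent
    names(p) <- x@clusterIds
    p
})

#' @rdname accessors
#' @export
setMethod("branchMutations", "PhyloTree", function(x, ...) {
    b <- x@branchMutations
    names(b) <- x@clusterIds
    b
})

#' @rdname accessors
#' @export
setMethod("branchCounts", "PhyloTree", function(x, ...) x@branchCounts)

#' @rdname accessors
#' @export
setMethod("mutations", "SyntheticPatient", function(x, ...) x@mutations)

#' @rdname accessors
#' @export
setMethod("segments", "SyntheticPatient", function(x, ...) x@segments)

#' @rdname accessors
#' @export
setMethod("truth", "SyntheticPatient", function(x, ...) x@truth)

setMethod("show", "SignatureCatalog", function(object) {
    cat("SignatureCatalog with", ncol(object@probs),
        "signatures over 96 channels\n")
    cat("  signatures:", paste(utils::head(colnames(object@probs), 5),
                               collapse = ", "),
        if (ncol(object@probs) > 5) "..." else "", "\n")
})

setMethod("show", "ClusterSet", function(object) {
    cat("ClusterSet:", nrow(object@ccf), "clusters over",
        ncol(object@ccf), "samples;",
        sum(!is.na(object@assignments)), "of",
        length(object@assignments), "mutations clustered\n")
    df <- data.frame(size = object@sizes,
                     round(object@ccf, 3),
                     merged = object@merged)
    print(df)
})

setMethod("show", "PhyloTree", function(object) {
    cat("PhyloTree with", length(object@clusterIds), "nodes (trunk:",
        object@clusterIds[is.na(object@parent)], ")\n")
    par <- ifelse(is.na(object@parent), "-",
                  object@clusterIds[object@parent])
    df <- data.frame(cluster = object@clusterIds, parent = par,
                     nMut = vapply(object@branchMutations, length, 1L),
                     round(object@ccf, 3))
    print(df, row.names = FALSE)
    if (length(object@alternatives))
        cat(length(object@alternatives),
            "alternative tree(s) consistent with the constraints\n")
})

setMethod("show", "WGDTiming", function(object) {
    cat(sprintf("WGD timing: t = %.3f [%.3f, %.3f] from %d mutations\n",
                object@t, object@ciLow, object@ciHigh, object@nMutations))
    cat("  mixture proportions:\n")
    print(round(object@pi, 4))
})

setMethod("show", "ExposureSolution", function(object) {
    cat(sprintf("ExposureSolution: %d signature(s), r = %.4f\n",
                length(object@signatures), object@r))
    print(round(exposures(object), 1))
})

setMethod("show", "SyntheticPatient", function(object) {
    cat("SyntheticPatient:", nrow(object@mutations), "mutations,",
        ncol(object@mutations), "samples,",
        length(unique(object@truth$branch_id)), "truth branches\n")
})
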