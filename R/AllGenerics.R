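#' @include AllClasses.R
NULL

#' Accessors for phyloCCF classes
#'
#' @param x An object.
#' @param ... Unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("altCounts", function(x, ...) standardGeneric("altCounts"))
#' @rdname accessors
#' @export
setGeneric("depths", function(x, ...) standardGeneric("depths"))
#' @rdname accessors
#' @export
setGeneric("purity", function(x, ...) standardGeneric("purity"))
#' @rdname accessors
#' @export
setGeneric("vaf", function(x, ...) standardGeneric("vaf"))
#' @rdname accessors
#' @export
setGeneric("ccf", function(x, ...) standardGeneric("ccf"))
#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x, ...) standardGeneric("clusterSizes"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(x, ...) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("memberships", function(x, ...) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setGeneric("signatureNames", function(x, ...) standardGeneric("signatureNames"))
#' @rdname accessors
#' @export
setGeneric("probs", function(x, ...) standardGeneric("probs"))
#' @rdname accessors
#' @export
setGeneric("exposures", function(x, ...) standardGeneric("exposures"))
#' @rdname accessors
#' @export
setGeneric("reconstructionR", function(x, ...) standardGeneric("reconstructionR"))
#' @rdname accessors
#' @export
setGeneric("wgdTimeEstimate", function(x, ...) standardGeneric("wgdTimeEstimate"))
#' @rdname accessors
#' @export
setGeneric("wgdCI", function(x, ...) standardGeneric("wgdCI"))
#' @rdname accessors
#' @export
setGeneric("mixtureProportions", function(x, ...) standardGeneric("mixtureProportions"))
#' @rdname accessors
#' @export
setGeneric("parentIndex", function(x, ...) standardGeneric("parentIndex"))
#' @rdname accessors
#' @export
setGeneric("branchMutations", function(x, ...) standardGeneric("branchMutations"))
#' @rdname accessors
#' @export
setGeneric("branchCounts", function(x, ...) standardGeneric("branchCounts"))
#' @rdname accessors
#' @export
setGeneric("mutations", function(x, ...) standardGeneric("mutations"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x, ...) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x, ...) standardGeneric("truth"))

#' Export a tree in Newick format
#'
#' @param x A [PhyloTree-class].
#' @param ... Passed to methods.
#' @export
setGeneric("exportNewick", function(x, ...) standardGeneric("exportNewick"))
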