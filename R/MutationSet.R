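#' @include AllClasses.R
NULL

#' Construct a MutationSet
#'
#' @param chrom Chromosome per mutation.
#' @param pos 1-based position (VCF convention).
#' @param ref,alt Reference and alternate alleles (for SVs, use ".").
#' @param class Mutation class: \code{substitution}, \code{insertion},
#'   \code{deletion} or \code{SV}. If \code{NULL}, inferred from ref/alt
#'   lengths.
#' @param X Matrix of variant read counts, mutations x samples.
#' @param n Matrix of total depths, same shape as \code{X}. A depth of 0
#'   marks an untyped site.
#' @param purity Named numeric vector of tumor purities, one per sample.
#' @param gene,consequence,channel Optional per-mutation annotation; channel
#'   is the trinucleotide channel label (see [channelNames()]).
#' @param ids Mutation identifiers; defaults to \code{chrom:pos_ref>alt}.
#' @return A [MutationSet-class].
#' @export
#' @examples
#' ms <- MutationSet(chrom = "chr1", pos = c(100, 200),
#'                   ref = c("A", "C"), alt = c("T", "G"),
#'                   X = cbind(P = c(10, 5), R = c(8, 0)),
#'                   n = cbind(P = c(20, 18), R = c(22, 25)),
#'                   purity = c(P = 0.8, R = 0.7))
#' vaf(ms)
MutationSet <- function(chrom, pos, ref, alt, class = NULL, X, n, purity,
                        gene = NULL, consequence = NULL, channel = NULL,
                        ids = NULL) {
    X <- as.matrix(X); n <- as.matrix(n)
    if (!identical(dim(X), dim(n)))
        stopf("variant-read and depth matrices must have identical shape")
    nmut <- nrow(X)
    chrom <- rep_len(as.character(chrom), nmut)
    pos <- rep_len(as.integer(pos), nmut)
    if (any(pos < 1L)) stopf("positions are 1-based and must be >= 1")
    if (is.null(class)) class <- inferMutationClass(ref, alt)
    bad <- which(X > n)
    if (length(bad))
        stopf("variant reads exceed depth at row %d", (bad[1L] - 1L) %% nmut + 1L)
    if (is.null(ids)) ids <- paste0(chrom, ":", pos, "_", ref, ">", alt)
    if (anyDuplicated(ids)) ids <- make.unique(ids)
    samples <- colnames(X) %||% names(purity)
    if (is.null(samples)) samples <- paste0("S", seq_len(ncol(X)))
    colnames(X) <- colnames(n) <- samples
    rownames(X) <- rownames(n) <- ids
    if (is.null(names(purity))) names(purity) <- samples
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    names(rr) <- ids
    rd <- S4Vectors::DataFrame(ref = as.character(ref),
                               alt = as.character(alt),
                               class = as.character(class))
    if (!is.null(gene)) rd$gene <- as.character(gene)
    if (!is.null(consequence)) rd$consequence <- as.character(consequence)
    if (!is.null(channel)) rd$channel <- as.character(channel)
    S4Vectors::mcols(rr) <- rd
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(alt = X, depth = n),
        rowRanges = rr,
        colData = S4Vectors::DataFrame(purity = unname(purity[samples]),
                                       row.names = samples))
    methods::new("MutationSet", se)
}

inferMutationClass <- function(ref, alt) {
    ifelse(nchar(ref) == 1L & nchar(alt) == 1L & ref != "." & alt != ".",
           "substitution",
           ifelse(nchar(alt) > nchar(ref), "insertion",
                  ifelse(nchar(ref) > nchar(alt), "deletion", "SV")))
}
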