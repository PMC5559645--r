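#' @include io.R phylogeny.R
NULL

#' Number of candidate signature combinations
#'
#' Counts all non-empty signature subsets of size up to `maxSize` from a
#' catalogue of `K` signatures: sum over k of choose(K, k). For the
#' 27-signature consensus catalogue with subsets up to 7 this is 1,285,623.
#'
#' @param K Catalogue size.
#' @param maxSize Largest subset size.
#' @return Count (numeric).
#' @export
#' @examples
#' countCombinations(27, 7)  # 1285623
countCombinations <- function(K, maxSize) {
    if (maxSize < 1 || maxSize > K)
        stopf("maxSize must lie in 1..K")
    sum(choose(K, seq_len(maxSize)))
}

#' Fit signature exposures for a fixed subset
#'
#' Solves the non-negative least-squares reconstruction of a 96-channel
#' spectrum from the chosen signature columns; exposures come out in
#' mutation counts (catalogue columns sum to 1). The fit is scored by the
#' Pearson correlation r between the observed and reconstructed spectrum.
#'
#' @param spectrum Numeric 96-vector of channel counts.
#' @param subset Signature names or column indices.
#' @param catalog A [SignatureCatalog-class].
#' @return A list: `exposures` (named, counts), `r`, `reconstructed`.
#' @export
fitExposures <- function(spectrum, subset, catalog) {
    spectrum <- as.numeric(spectrum)
    if (length(spectrum) != 96L) stopf("spectrum must have 96 channels")
    if (sum(spectrum) <= 0) stopf("spectrum is all zero")
    if (!length(subset)) stopf("subset must be non-empty")
    P <- probs(catalog)
    if (is.character(subset)) {
        miss <- setdiff(subset, colnames(P))
        if (length(miss)) stopf("unknown signature %s", miss[1L])
    }
    A <- P[, subset, drop = FALSE]
    x <- .nnls_fit(A, spectrum)
    names(x) <- colnames(A)
    recon <- as.numeric(A %*% x)
    r <- if (stats::sd(recon) == 0) 0 else stats::cor(spectrum, recon)
    list(exposures = x, r = r, reconstructed = recon)
}

#' Select a signature model by exhaustive search
#'
#' Evaluates every subset of up to `maxSize` signatures by NNLS refit and
#' applies the model-selection rules: a solution is inadmissible when any
#' non-exempt member signature contributes less than `minShare` of the
#' mutations or fewer than `minCount` mutations; among admissible solutions
#' the best Pearson r of each size enters a nested ladder where a larger
#' model replaces the accepted smaller one only if it improves r by at
#' least `minImprovement`. Exempt signatures (by default Signature.1 and
#' Signature.5, reflecting continuously active endogenous processes) may
#' stay at any exposure but are never force-included.
#'
#' @param spectrum Numeric 96-vector of channel counts (total > 20).
#' @param catalog A [SignatureCatalog-class].
#' @param maxSize Largest subset size, default 7.
#' @param minShare Minimum fraction contributed by a non-exempt signature,
#'   default 0.02.
#' @param minCount Minimum mutations contributed, default 50.
#' @param minImprovement Minimum Pearson-r gain per added signature,
#'   default 0.02.
#' @param exempt Signature names exempt from the contribution rule.
#' @return An [ExposureSolution-class]. If no subset is admissible the best
#'   single-signature fit is returned with a warning (audit flag
#'   `fallback`).
#' @export
selectModel <- function(spectrum, catalog, maxSize = 7, minShare = 0.02,
                        minCount = 50, minImprovement = 0.02,
                        exempt = c("Signature.1", "Signature.5")) {
    spectrum <- as.numeric(spectrum)
    total <- sum(spectrum)
    if (total <= 20) stopf("spectrum must contain more than 20 mutations")
    P <- probs(catalog)
    K <- ncol(P)
    maxSize <- min(maxSize, K)
    ## order-invariance: search over a canonical column order
    colOrder <- order(colnames(P))
    P <- P[, colOrder, drop = FALSE]
    G <- crossprod(P)
    b <- as.numeric(crossprod(P, spectrum))
    res <- .sig_search(G, b, sum(spectrum), sum(spectrum^2), total, 96L,
                       as.integer(maxSize),
                       colnames(P) %in% exempt, minShare, minCount)
    perSize <- res$perSize
    audit <- list(nEvaluated = res$nEvaluated,
                  nInadmissible = res$nInadmissible,
                  bestRPerSize = vapply(perSize, function(z)
                      if (is.null(z)) NA_real_ else z$r, numeric(1)),
                  ladder = character(0), fallback = FALSE)

    accepted <- NULL
    for (k in seq_len(maxSize)) {
        cand <- perSize[[k]]
        if (is.null(cand)) next
        if (is.null(accepted)) {
            accepted <- cand
            audit$ladder <- c(audit$ladder,
                sprintf("size %d accepted (r = %.4f)", k, cand$r))
        } else if (cand$r >= accepted$r + minImprovement) {
            audit$ladder <- c(audit$ladder,
                sprintf("size %d accepted (r %.4f -> %.4f)", k,
                        accepted$r, cand$r))
            accepted <- cand
        } else {
            audit$ladder <- c(audit$ladder,
                sprintf("size %d rejected (gain %.4f < %.2f)", k,
                        cand$r - accepted$r, minImprovement))
        }
    }
    if (is.null(accepted)) {
        warnf("no admissible solution; returning best single-signature fit")
        audit$fallback <- TRUE
        accepted <- list(r = res$fallback$r,
                         subset = res$fallback$signature,
                         exposures = res$fallback$exposure)
    }
    sel <- colnames(P)[accepted$subset]
    o <- order(match(sel, colnames(probs(catalog))))  # catalogue order
    methods::new("ExposureSolution",
                 signatures = sel[o],
                 exposures = as.numeric(accepted$exposures)[o],
                 r = accepted$r, total = total, audit = audit)
}

#' Spectrum of a mutation set
#'
#' Tabulates trinucleotide channels into the canonical 96-vector.
#'
#' @param channels Character vector of channel labels.
#' @return Named integer 96-vector.
#' @export
spectrumFromChannels <- function(channels) {
    chan <- channelNames()
    bad <- setdiff(unique(channels), chan)
    if (length(bad)) stopf("unknown channel label %s", bad[1L])
    tab <- table(factor(channels, levels = chan))
    stats::setNames(as.integer(tab), chan)
}

#' Per-branch signature refitting
#'
#' Builds the 96-channel spectrum of every tree branch from the mutations'
#' trinucleotide channels and runs [selectModel()] on each branch with more
#' than `minMutations` substitutions. Smaller branches are skipped with a
#' reason.
#'
#' @param tree A [PhyloTree-class].
#' @param x The [MutationSet-class] the tree was built from (must carry a
#'   `channel` rowData column for substitutions).
#' @param catalog A [SignatureCatalog-class].
#' @param minMutations Branch-size threshold, default 20 (strictly more
#'   required).
#' @param ... Passed to [selectModel()].
#' @return A list with one entry per branch: an [ExposureSolution-class] or
#'   a character skip reason.
#' @export
branchSignatures <- function(tree, x, catalog, minMutations = 20, ...) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"channel" %in% colnames(rd))
        stopf("mutations carry no trinucleotide channel annotation")
    chanMap <- stats::setNames(rd$channel, rownames(x))
    isSub <- stats::setNames(rd$class == "substitution", rownames(x))
    out <- vector("list", length(tree@clusterIds))
    names(out) <- tree@clusterIds
    for (k in seq_along(out)) {
        ids <- tree@branchMutations[[k]]
        ids <- ids[isSub[ids] %in% TRUE]
        if (length(ids) <= minMutations) {
            out[[k]] <- sprintf("skipped: %d mutations (need > %d)",
                                length(ids), minMutations)
            next
        }
        if (anyNA(chanMap[ids]))
            stopf("mutation %s has no trinucleotide context",
                  ids[which(is.na(chanMap[ids]))[1L]])
        out[[k]] <- selectModel(spectrumFromChannels(chanMap[ids]),
                                catalog, ...)
    }
    out
}
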