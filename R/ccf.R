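#' @include MutationSet.R
NULL

#' Expected variant allele fraction
#'
#' For a mutation on `m` of `c` tumor copies, carried by a fraction `p` of
#' tumor cells (the cancer cell fraction), in a sample of purity `rho`, the
#' expected VAF is
#' \deqn{f = \frac{\rho m p}{\rho c + 2 (1 - \rho)}}
#' i.e. mutant copies over all copies at the locus, counting two copies per
#' contaminating normal cell.
#'
#' @param rho Purity in (0, 1].
#' @param c Total copy number at the site, >= 1.
#' @param m Multiplicity (mutated copies per tumor cell), 1 <= m <= c.
#' @param p Cancer cell fraction in [0, 1].
#' @return Expected VAF in [0, 1]. Vectorised over all arguments.
#' @export
#' @examples
#' expectedVAF(1, 4, 2, 1)        # early-clonal tetraploid: 0.5
#' expectedVAF(0.5, 4, 1, 0.8)    # 0.1333
expectedVAF <- function(rho, c, m, p) {
    if (any(rho <= 0 | rho > 1)) stopf("purity must lie in (0, 1]")
    if (any(c < 1)) stopf("total copy number must be >= 1")
    if (any(m < 1)) stopf("multiplicity must be >= 1")
    if (any(m > c)) stopf("multiplicity cannot exceed total copy number")
    if (any(p < 0 | p > 1)) stopf("CCF must lie in [0, 1]")
    rho * m * p / (rho * c + 2 * (1 - rho))
}

## Inverse: CCF implied by an observed VAF at multiplicity m.
impliedCCF <- function(v, rho, c, m) {
    v * (rho * c + 2 * (1 - rho)) / (rho * m)
}

#' Estimate mutation multiplicity from observed VAF
#'
#' For near-clonal mutations the multiplicity is the integer in 1..c whose
#' clonal expected VAF best matches the observation; subclonal mutations are
#' assigned multiplicity 1 (a subclonal mutation arises on one copy, after
#' any copy-number gain). "Near-clonal" means the CCF implied at
#' multiplicity 1 reaches `clonalCutoff`.
#'
#' @param X,n Variant reads and depth (vectors over sites or samples).
#' @param rho Purity.
#' @param c Total copy number at each site.
#' @param clonalCutoff Implied-CCF threshold above which multiplicities > 1
#'   are considered (default 0.9).
#' @return A list with integer `m` and the CCF implied at that multiplicity
#'   (capped at 1.2). Sites with n = 0 get `m = NA`.
#' @export
#' @examples
#' estimateMultiplicity(50, 100, 1, 4)$m   # 2
#' estimateMultiplicity(25, 100, 1, 4)$m   # 1
estimateMultiplicity <- function(X, n, rho, c, clonalCutoff = 0.9) {
    len <- max(length(X), length(n), length(c))
    X <- rep_len(X, len); n <- rep_len(n, len)
    c <- rep_len(as.integer(c), len); rho <- rep_len(rho, len)
    m <- rep(NA_integer_, len)
    p <- rep(NA_real_, len)
    typed <- n > 0 & c >= 1
    v <- ifelse(typed, X / n, NA_real_)
    ccf1 <- impliedCCF(v, rho, c, 1)
    for (i in which(typed)) {
        if (ccf1[i] >= clonalCutoff) {
            cand <- seq_len(c[i])
            resid <- abs(v[i] - expectedVAF(rho[i], c[i], cand, 1))
            m[i] <- cand[which.min(resid)]
        } else m[i] <- 1L
        p[i] <- min(impliedCCF(v[i], rho[i], c[i], m[i]), 1.2)
    }
    list(m = m, ccf = p)
}

#' Quality-control filter for clustering
#'
#' Excludes mutations that cannot be interpreted consistently across related
#' samples: (a) mutations overlapping a region deleted (total copy number 0,
#' clonal) in any sample, where copy-number loss rather than clonal
#' structure could explain absence (reason \code{"lost-region"}); (b)
#' mutations falling outside every segment in at least one sample, where the
#' copy number is undefined (reason \code{"undefined-CN"}).
#'
#' @param x A [MutationSet-class].
#' @param segments Segment \linkS4class{GRanges} covering all samples of `x`.
#' @return A list: `retained` (MutationSet subset), `excluded` (data.frame of
#'   mutation_id, reason), `retainedFraction`.
#' @export
qcFilter <- function(x, segments) {
    samples <- colnames(x)
    missing <- setdiff(samples, unique(segments$sample))
    if (length(missing))
        stopf("no segments provided for sample %s", missing[1L])
    rr <- SummarizedExperiment::rowRanges(x)
    reason <- rep(NA_character_, nrow(x))
    for (s in samples) {
        gs <- segments[segments$sample == s]
        ov <- GenomicRanges::findOverlaps(rr, gs, select = "first")
        outside <- is.na(ov)
        lost <- !outside & gs$totalCN[ifelse(outside, 1L, ov)] == 0 &
            gs$subclonalFraction[ifelse(outside, 1L, ov)] >= 1
        reason[lost & is.na(reason)] <- "lost-region"
        reason[outside & is.na(reason)] <- "undefined-CN"
    }
    keep <- is.na(reason)
    excluded <- data.frame(mutation_id = rownames(x)[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
    if (!any(keep))
        warnf("no mutations retained after QC")
    list(retained = x[keep, ], excluded = excluded,
         retainedFraction = mean(keep))
}

#' Annotate copy number, multiplicity and CCF
#'
#' Looks up the total copy number at every mutation in every sample,
#' estimates multiplicity with [estimateMultiplicity()], and adds
#' \code{"totalCN"}, \code{"multiplicity"} and \code{"ccf"} assays. Run
#' [qcFilter()] first so every retained mutation has defined copy number.
#'
#' @param x A [MutationSet-class].
#' @param segments Segment \linkS4class{GRanges}.
#' @param clonalCutoff Passed to [estimateMultiplicity()].
#' @return `x` with the three assays added. Mutations untyped (n = 0) in
#'   every sample are flagged unassignable with a warning.
#' @export
computeCCF <- function(x, segments, clonalCutoff = 0.9) {
    samples <- colnames(x)
    rr <- SummarizedExperiment::rowRanges(x)
    X <- altCounts(x); n <- depths(x)
    rho <- purity(x)
    cn <- mult <- pccf <- matrix(NA_real_, nrow(x), length(samples),
                                 dimnames = dimnames(X))
    for (s in samples) {
        gs <- segments[segments$sample == s]
        hit <- GenomicRanges::findOverlaps(rr, gs, select = "first")
        if (anyNA(hit))
            stopf("mutation %s has undefined copy number in sample %s; run qcFilter first",
                  rownames(x)[which(is.na(hit))[1L]], s)
        cn[, s] <- gs$totalCN[hit]
        est <- estimateMultiplicity(X[, s], n[, s], rho[s], cn[, s],
                                    clonalCutoff)
        mult[, s] <- est$m
        pccf[, s] <- est$ccf
    }
    untyped <- rowSums(n > 0) == 0
    if (any(untyped))
        warnf("%d mutation(s) untyped in every sample are unassignable",
              sum(untyped))
    SummarizedExperiment::assay(x, "totalCN") <- cn
    SummarizedExperiment::assay(x, "multiplicity") <- mult
    SummarizedExperiment::assay(x, "ccf") <- pccf
    x
}
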