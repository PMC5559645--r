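#' @include ccf.R AllClasses.R
NULL

#' Cluster mutations across related samples with a Dirichlet process
#'
#' Gibbs-samples a Dirichlet-process binomial mixture over cancer cell
#' fractions in as many dimensions as there are samples. Each mutation's
#' variant reads are modelled as
#' \code{X[i,s] ~ Binomial(n[i,s], expectedVAF(rho_s, c_is, m_is, p_ks))}
#' with independence across samples, so purity, copy number and multiplicity
#' enter through the expected VAF. Cluster CCFs move on a discrete grid over
#' [0, 1.2] (values above 1 absorb multiplicity misestimates) and are
#' truncated to [0, 1] for reporting and tree building. The concentration
#' parameter carries a Gamma(1,1) hyperprior resampled each sweep. The
#' posterior partition is the sampled partition maximising the posterior
#' expected adjusted Rand index against the pairwise co-clustering matrix.
#'
#' Mutations are canonically ordered by id before sampling, so the result is
#' invariant to input row order at a fixed seed. Clusters smaller than
#' `minClusterSize` are merged into the nearest cluster (Euclidean distance
#' in CCF space) and the receiving cluster flagged.
#'
#' @param x A [MutationSet-class] carrying \code{"totalCN"} and
#'   \code{"multiplicity"} assays (see [computeCCF()]).
#' @param iterations Total Gibbs sweeps (default 1000).
#' @param burnIn Discarded sweeps (default 500); must be < `iterations`.
#' @param seed Integer seed.
#' @param minClusterSize Minimum reported cluster size; default
#'   \code{max(5, ceiling(0.01 * nrow(x)))}.
#' @param gridStep CCF grid resolution (default 0.01).
#' @param nAux Auxiliary components for the non-conjugate CRP update.
#' @return A [ClusterSet-class].
#' @export
dpCluster <- function(x, iterations = 1000, burnIn = 500, seed = 1,
                      minClusterSize = NULL, gridStep = 0.01, nAux = 3) {
    if (iterations <= burnIn)
        stopf("iterations (%d) must exceed burnIn (%d)", iterations, burnIn)
    if (nrow(x) < 1L) stopf("at least one mutation required")
    if (is.null(minClusterSize))
        minClusterSize <- max(5L, ceiling(0.01 * nrow(x)))

    ## canonical order: invariance to input row permutation
    ord <- order(rownames(x))
    xo <- x[ord, ]
    X <- altCounts(xo); n <- depths(xo)
    cn <- SummarizedExperiment::assay(xo, "totalCN")
    m <- SummarizedExperiment::assay(xo, "multiplicity")
    rho <- purity(xo)
    m[is.na(m)] <- 1
    phi <- sweep(m, 2, rho, "*") /
        (sweep(cn, 2, rho, "*") + matrix(2 * (1 - rho), nrow(xo),
                                         ncol(xo), byrow = TRUE))
    set.seed(seed)
    fit <- .dp_gibbs(X, n, phi, as.integer(iterations), as.integer(burnIn),
                     as.integer(nAux), 1.2, gridStep)
    part <- fit$partition

    ## relabel canonically: decreasing size, ties by decreasing mean CCF
    cs <- makeClusterSummary(X, n, phi, part, gridStep,
                             mutationIds = rownames(xo),
                             samples = colnames(xo))
    cs <- mergeSmallClusters(cs, X, n, phi, gridStep, minClusterSize)
    cs@diagnostics <- c(cs@diagnostics,
                        list(iterations = iterations, burnIn = burnIn,
                             alphaTrace = fit$alphaTrace,
                             kTrace = fit$kTrace, pear = fit$pear,
                             minClusterSize = minClusterSize))
    cs
}

## Summarise a hard partition: per-cluster CCF posterior median and 95%
## credible interval from the exact grid posterior, and posterior membership
## probabilities from cluster weights and point CCFs.
makeClusterSummary <- function(X, n, phi, part, gridStep, mutationIds,
                               samples) {
    labs <- sort(unique(part))
    K <- length(labs)
    S <- ncol(X)
    grid <- seq(0, 1.2, by = gridStep)
    ccf <- lo <- hi <- matrix(0, K, S, dimnames = list(NULL, samples))
    sizes <- integer(K)
    for (k in seq_len(K)) {
        members <- which(part == labs[k])
        sizes[k] <- length(members)
        post <- .ccf_grid_posterior(X, n, phi, members, 1.2, gridStep)
        for (s in seq_len(S)) {
            cdf <- cumsum(post[, s])
            ccf[k, s] <- grid[which(cdf >= 0.5)[1L]]
            lo[k, s] <- grid[which(cdf >= 0.025)[1L]]
            hi[k, s] <- grid[which(cdf >= 0.975)[1L]]
        }
    }
    o <- order(-sizes, -rowSums(ccf))
    relab <- match(match(part, labs), o)
    asn <- as.integer(relab)
    memb <- membershipProbabilities(X, n, phi, ccf[o, , drop = FALSE],
                                    sizes[o])
    methods::new("ClusterSet",
                 ccf = pmin(ccf[o, , drop = FALSE], 1.2),
                 ccfLower = lo[o, , drop = FALSE],
                 ccfUpper = hi[o, , drop = FALSE],
                 sizes = sizes[o], assignments = asn,
                 memberships = memb, mutationIds = mutationIds,
                 merged = rep(FALSE, K), diagnostics = list())
}

## P(cluster k | mutation i) from cluster weights and point CCFs; ties are
## broken toward the more ancestral cluster (larger CCF sum) downstream.
membershipProbabilities <- function(X, n, phi, ccf, sizes) {
    K <- nrow(ccf); N <- nrow(X)
    ll <- matrix(0, N, K)
    for (k in seq_len(K)) {
        f <- pmin(pmax(sweep(phi, 2, pmin(ccf[k, ], 1.2), "*"), 1e-12),
                  1 - 1e-9)
        lk <- stats::dbinom(X, n, f, log = TRUE)
        lk[n == 0] <- 0
        ll[, k] <- rowSums(lk) + log(sizes[k] / sum(sizes))
    }
    w <- exp(ll - apply(ll, 1, max))
    w / rowSums(w)
}

mergeSmallClusters <- function(cs, X, n, phi, gridStep, minClusterSize) {
    repeat {
        small <- which(cs@sizes < minClusterSize)
        if (!length(small) || nrow(cs@ccf) <= 1L) return(cs)
        k <- small[which.min(cs@sizes[small])]
        d <- sqrt(rowSums(sweep(cs@ccf, 2, cs@ccf[k, ], "-")^2))
        d[k] <- Inf
        tgt <- which.min(d)
        part <- cs@assignments
        part[part == k] <- tgt
        part <- match(part, sort(unique(part)))
        flaggedCcf <- rbind(cs@ccf[cs@merged, , drop = FALSE],
                            cs@ccf[tgt, , drop = FALSE])
        new <- makeClusterSummary(X, n, phi, part, gridStep,
                                  cs@mutationIds,
                                  colnames(cs@ccf))
        ## re-flag receivers (nearest new cluster to each flagged old CCF)
        for (r in seq_len(nrow(flaggedCcf))) {
            dd <- sqrt(rowSums(sweep(new@ccf, 2, flaggedCcf[r, ], "-")^2))
            new@merged[which.min(dd)] <- TRUE
        }
        cs <- new
    }
}
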