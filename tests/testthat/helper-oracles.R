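# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (enumeration, closed form, brute
# force) and independent of the package's implementation paths.

# Exact upper binomial tail by direct summation.
binomTailOracle <- function(X, n, e) {
    if (X == 0) return(1)
    k <- X:n
    sum(choose(n, k) * e^k * (1 - e)^(n - k))
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the same margins whose
# probability does not exceed the observed one (matching fisher.test).
fisherOracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    xs <- lo:hi
    pr <- dhyper(xs, m, n, k)
    pObs <- dhyper(a, m, n, k)
    sum(pr[pr <= pObs * (1 + 1e-7)])
}

# 1-D two-component binomial mixture EM with free success probabilities
# (the oracle for single-sample clustering means).
emBinom1D <- function(X, n, K = 2, iters = 500) {
    p <- seq(0.1, 0.9, length.out = K)
    w <- rep(1 / K, K)
    for (it in seq_len(iters)) {
        ll <- sapply(seq_len(K), function(k)
            dbinom(X, n, p[k], log = TRUE) + log(w[k]))
        post <- exp(ll - apply(ll, 1, max))
        post <- post / rowSums(post)
        w <- colMeans(post)
        p <- colSums(post * X) / colSums(post * n)
    }
    list(p = sort(p), w = w[order(p)])
}

# Brute-force enumeration of all rooted cluster arrangements satisfying
# per-sample CCF dominance and the sibling pigeonhole sum constraint.
# Returns a list of parent vectors (NA marks the root).
enumerateTreesOracle <- function(cc, tol = 0.05) {
    K <- nrow(cc)
    trunk <- which(rowSums(cc >= 1 - tol) == ncol(cc))[1]
    others <- setdiff(seq_len(K), trunk)
    if (!length(others)) return(list(structure(rep(NA_integer_, K))))
    choices <- rep(list(seq_len(K)), length(others))
    out <- list()
    grid <- do.call(expand.grid, choices)
    for (r in seq_len(nrow(grid))) {
        par <- rep(NA_integer_, K)
        par[others] <- as.integer(unlist(grid[r, ]))
        if (any(par[others] == others)) next
        # acyclic, rooted at trunk
        ok <- TRUE
        for (i in others) {
            seen <- integer(0); j <- i
            while (!is.na(par[j])) {
                if (j %in% seen) { ok <- FALSE; break }
                seen <- c(seen, j); j <- par[j]
            }
            if (!ok || j != trunk) { ok <- FALSE; break }
        }
        if (!ok) next
        # dominance along each edge
        for (i in others)
            if (any(cc[i, ] > cc[par[i], ] + tol)) { ok <- FALSE; break }
        if (!ok) next
        # sibling pigeonhole
        for (p in seq_len(K)) {
            kids <- which(!is.na(par) & par == p)
            if (length(kids) >= 2 &&
                any(colSums(cc[kids, , drop = FALSE]) > cc[p, ] + tol)) {
                ok <- FALSE; break
            }
        }
        if (ok) out[[length(out) + 1]] <- par
    }
    out
}

# Grid search on the 1-simplex for a 2-signature exposure fit (oracle for
# NNLS on noise-free mixtures).
gridFit2 <- function(spectrum, cols, step = 1e-3) {
    total <- sum(spectrum)
    best <- c(NA, Inf)
    for (a in seq(0, 1, by = step)) {
        recon <- total * (a * cols[, 1] + (1 - a) * cols[, 2])
        rss <- sum((spectrum - recon)^2)
        if (rss < best[2]) best <- c(a, rss)
    }
    c(fit1 = best[1] * total, fit2 = (1 - best[1]) * total)
}

# Map inferred cluster labels onto truth branches (majority vote) and
# return the fraction of mutations assigned to the right branch.
coClusteringAccuracy <- function(assign, truthBranch) {
    stopifnot(length(assign) == length(truthBranch))
    map <- tapply(truthBranch, assign, function(z)
        names(sort(table(z), decreasing = TRUE))[1])
    mean(map[as.character(assign)] == truthBranch)
}

# A small two-sample MutationSet with explicit counts.
toyMutationSet <- function() {
    MutationSet(chrom = c("chr1", "chr1", "chr2"), pos = c(100, 500, 900),
                ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                X = cbind(P = c(10L, 4L, 0L), R = c(12L, 0L, 6L)),
                n = cbind(P = c(20L, 18L, 15L), R = c(25L, 22L, 14L)),
                purity = c(P = 0.9, R = 0.8))
}

# Diploid whole-chromosome segments for both toy samples.
toySegments <- function(samples = c("P", "R")) {
    do.call(c, lapply(samples, function(s)
        segmentTable(chrom = c("chr1", "chr2"), start = c(0, 0),
                     end = c(1e6, 1e6), totalCN = 2, minorCN = 1,
                     sample = s)))
}

# Minimal cancer-gene table exercising all four annotation categories.
toyGeneTable <- function() {
    data.frame(
        gene = c("ONC1", "ONC1", "TSG1", "TSG1", "BOTH1"),
        role = c("oncogene", "oncogene", "TSG", "TSG", "both"),
        hotspot_pos = c(1000L, 2000L, 3000L, 4000L, 5000L),
        hotspot_count = c(10L, 3L, 2L, 0L, 5L),
        canonical = c(TRUE, FALSE, FALSE, FALSE, FALSE),
        splice_site = c(FALSE, FALSE, FALSE, TRUE, FALSE),
        stringsAsFactors = FALSE)
}

# Simulation config for a well-separated two-sample patient (CCF gaps
# >= 0.2, depth 80, substitutions only) used by the recovery suites.
wellSeparatedConfig <- function(seed, nTrunk = 300, nPrivate = 100,
                                depth = 80) {
    tree <- defaultCloneTree(nTrunk = nTrunk, nPrivate = nPrivate)
    for (i in seq_along(tree)) tree[[i]]$indelFraction <- 0
    simulationConfig(depthMean = depth, purity = c(primary = 0.9,
                                                   relapse = 0.85),
                     cloneTree = tree, nNullSites = 0,
                     lostFraction = 0, gapFraction = 0, seed = seed)
}
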