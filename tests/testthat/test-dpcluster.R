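# Build a MutationSet directly from known CCFs so clustering behaviour can
# be tested without the full simulator.
mutationSetFromCCF <- function(ccfMat, nPer, depth, rho, seed) {
    set.seed(seed)
    S <- ncol(ccfMat)
    rows <- do.call(rbind, lapply(seq_len(nrow(ccfMat)), function(k)
        matrix(rep(ccfMat[k, ], nPer[k]), ncol = S, byrow = TRUE)))
    N <- nrow(rows)
    n <- matrix(rpois(N * S, depth), N, S)
    f <- sweep(rows, 2, rho / (2 * rho + 2 * (1 - rho)), "*")
    X <- matrix(rbinom(N * S, n, pmin(f, 1)), N, S)
    samples <- paste0("S", seq_len(S))
    colnames(X) <- colnames(n) <- samples
    ms <- MutationSet(chrom = "chr1", pos = seq_len(N), ref = "C",
                      alt = "T", X = X, n = n,
                      purity = stats::setNames(rep(rho, S), samples))
    seg <- do.call(c, lapply(samples, function(s)
        segmentTable(chrom = "chr1", start = 0, end = 1e7, totalCN = 2,
                     minorCN = 1, sample = s)))
    computeCCF(ms, seg)
}

test_that("a single clonal population yields one dominant cluster", {
    ms <- mutationSetFromCCF(matrix(c(1, 1), 1), nPer = 300, depth = 100,
                             rho = 1, seed = 2)
    cl <- dpCluster(ms, iterations = 400, burnIn = 200, seed = 7)
    expect_gte(max(clusterSizes(cl)) / nrow(ms), 0.99)
    expect_equal(unname(ccf(cl)[1, ]), c(1, 1), tolerance = 0.05)
})

test_that("two well-separated clusters are recovered with correct CCFs", {
    ccfMat <- rbind(c(1, 1), c(0.5, 0))
    ms <- mutationSetFromCCF(ccfMat, nPer = c(300, 300), depth = 80,
                             rho = 1, seed = 3)
    cl <- dpCluster(ms, iterations = 600, burnIn = 300, seed = 11)
    expect_identical(nrow(ccf(cl)), 2L)
    truthBranch <- rep(c("trunk", "sub"), c(300, 300))
    names(truthBranch) <- sprintf("chr1:%d_C>T", seq_len(600))
    acc <- coClusteringAccuracy(assignments(cl),
                                truthBranch[names(assignments(cl))])
    expect_gte(acc, 0.9)
    o <- order(-rowSums(ccf(cl)))
    expect_equal(unname(ccf(cl)[o[1], ]), c(1, 1), tolerance = 0.06)
    expect_equal(unname(ccf(cl)[o[2], ]), c(0.5, 0), tolerance = 0.06)
})

test_that("single-sample clustering matches a 1-D EM binomial oracle", {
    ccfMat <- matrix(c(1, 0.5), 2)
    ms <- mutationSetFromCCF(ccfMat, nPer = c(250, 250), depth = 100,
                             rho = 1, seed = 4)
    cl <- dpCluster(ms, iterations = 600, burnIn = 300, seed = 5)
    oracle <- emBinom1D(altCounts(ms)[, 1], depths(ms)[, 1], K = 2)
    inferredVAF <- sort(ccf(cl)[, 1] / 2)   # diploid, purity 1: f = p/2
    expect_identical(length(inferredVAF), 2L)
    expect_lt(max(abs(inferredVAF - oracle$p)), 0.05)
})

test_that("clustering is invariant to mutation input order", {
    ms <- mutationSetFromCCF(rbind(c(1, 1), c(0.4, 0.9)),
                             nPer = c(150, 150), depth = 80, rho = 0.9,
                             seed = 6)
    cl1 <- dpCluster(ms, iterations = 300, burnIn = 150, seed = 9)
    perm <- sample(nrow(ms))
    cl2 <- dpCluster(ms[perm, ], iterations = 300, burnIn = 150, seed = 9)
    a1 <- assignments(cl1)
    a2 <- assignments(cl2)
    expect_identical(a1[sort(names(a1))], a2[sort(names(a2))])
    expect_equal(ccf(cl1), ccf(cl2))
})

test_that("clusters below the size floor merge into their neighbours", {
    ms <- mutationSetFromCCF(rbind(c(1, 1), c(0.5, 0.5)),
                             nPer = c(200, 3), depth = 60, rho = 1,
                             seed = 8)
    cl <- dpCluster(ms, iterations = 300, burnIn = 150, seed = 2,
                    minClusterSize = 5)
    expect_true(all(clusterSizes(cl) >= 5))
    expect_identical(sum(clusterSizes(cl)), 203L)
})

test_that("invalid sweep configuration errors", {
    ms <- mutationSetFromCCF(matrix(c(1, 1), 1), nPer = 20, depth = 50,
                             rho = 1, seed = 1)
    expect_error(dpCluster(ms, iterations = 100, burnIn = 100),
                 "must exceed")
})

test_that("trunk CCF is covered by the credible interval across replicates", {
    hits <- 0L
    reps <- 10L
    for (seed in seq_len(reps)) {
        ms <- mutationSetFromCCF(rbind(c(1, 1), c(0.45, 0.1)),
                                 nPer = c(120, 80), depth = 80, rho = 0.9,
                                 seed = 100 + seed)
        cl <- dpCluster(ms, iterations = 300, burnIn = 150, seed = seed)
        trunkIdx <- which.max(rowSums(ccf(cl)))
        covered <- all(cl@ccfLower[trunkIdx, ] <= 1 &
                       cl@ccfUpper[trunkIdx, ] >= 1 - 1e-9)
        hits <- hits + covered
    }
    expect_gte(hits / reps, 0.9)
})
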