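test_that("simulation is deterministic given the seed", {
    p1 <- simulatePatient(simulationConfig(seed = 11))
    p2 <- simulatePatient(simulationConfig(seed = 11))
    expect_identical(altCounts(mutations(p1)), altCounts(mutations(p2)))
    expect_identical(depths(mutations(p1)), depths(mutations(p2)))
    expect_identical(truth(p1), truth(p2))
    p3 <- simulatePatient(simulationConfig(seed = 12))
    expect_false(identical(altCounts(mutations(p1)),
                           altCounts(mutations(p3))))
})

test_that("trunk-only diploid patient at purity 1 has mean VAF near 0.5", {
    tree <- list(list(id = "trunk", parent = NA,
                      ccf = c(primary = 1, relapse = 1), nMut = 1000,
                      sigWeights = c(Signature.1 = 1),
                      indelFraction = 0, deletionFraction = 0))
    cfg <- simulationConfig(purity = c(primary = 1, relapse = 1),
                            cloneTree = tree, nNullSites = 0,
                            lostFraction = 0, gapFraction = 0,
                            depthMean = 60, seed = 5)
    p <- simulatePatient(cfg)
    v <- vaf(mutations(p))
    # X ~ Binom(n, 0.5): the SE of the mean VAF over 1000 sites is below
    # sqrt(0.25 / (1000 * 60)); allow 3 SE
    se <- sqrt(0.25 / (1000 * 60))
    expect_lt(abs(mean(v[, 1]) - 0.5), 3 * se)
    expect_lt(abs(mean(v[, 2]) - 0.5), 3 * se)
})

test_that("CCF monotonicity violations are rejected naming the branch", {
    tree <- defaultCloneTree()
    tree[[2]]$ccf <- c(primary = 0.8, relapse = 0)   # parent trunk ok
    tree[[2]]$parent <- "recurrence_private"          # parent has CCF 0
    expect_error(simulationConfig(cloneTree = tree),
                 "primary_private violates CCF monotonicity")
    tree2 <- defaultCloneTree()
    tree2[[1]]$ccf <- c(primary = 0.9, relapse = 1)
    expect_error(simulationConfig(cloneTree = tree2), "trunk")
})

test_that("mean observed VAF per branch converges to the analytic value", {
    # depth 10000: binomial noise is negligible, tolerance 1%
    tree <- defaultCloneTree(nTrunk = 150, nPrivate = 120)
    for (i in seq_along(tree)) tree[[i]]$indelFraction <- 0
    cfg <- simulationConfig(purity = c(primary = 0.8, relapse = 0.7),
                            cloneTree = tree, depthMean = 10000,
                            nNullSites = 0, lostFraction = 0,
                            gapFraction = 0, seed = 9)
    p <- simulatePatient(cfg)
    v <- vaf(mutations(p))
    tr <- truth(p)
    for (br in unique(tr$branch_id)) {
        rows <- tr$branch_id == br
        for (s in c("primary", "relapse")) {
            ccfs <- tr[rows, paste0("true_ccf_", s)][1]
            rho <- purity(mutations(p))[s]
            fExp <- if (ccfs > 0) expectedVAF(rho, 2, 1, ccfs) else 0.005
            expect_lt(abs(mean(v[rows, s]) - fExp), 0.01)
        }
    }
})

test_that("lineage monotonicity of truth CCFs holds in generated patients", {
    for (seed in 1:5) {
        p <- simulatePatient(simulationConfig(seed = seed))
        tr <- truth(p)
        cfg <- p@config
        ids <- vapply(cfg$cloneTree, `[[`, "", "id")
        for (br in cfg$cloneTree) {
            if (is.na(br$parent)) next
            parent <- cfg$cloneTree[[match(br$parent, ids)]]
            expect_true(all(br$ccf <= parent$ccf + 1e-9))
        }
        expect_true(all(table(tr$mutation_id) == 1))
    }
})

test_that("sampled spectra follow the configured mixture", {
    ctl <- syntheticSignatureCatalog()
    expect_identical(sum(sampleSpectrum(c(Signature.1 = 1), ctl, 0)), 0L)
    # single signature: chi-square GOF against the generating column
    sp <- sampleSpectrum(c(Signature.4 = 1), ctl, 10000, seed = 3)
    pcol <- probs(ctl)[, "Signature.4"]
    keep <- pcol > 1e-6
    gof <- suppressWarnings(
        chisq.test(sp[keep], p = pcol[keep] / sum(pcol[keep])))
    expect_gt(gof$p.value, 0.01)
    # 50/50 mix: expected channel vector is the average of the two columns
    w <- c(Signature.1 = 0.5, Signature.2 = 0.5)
    expected <- as.numeric(probs(ctl)[, names(w)] %*% w)
    expect_equal(expected,
                 as.numeric((probs(ctl)[, "Signature.1"] +
                             probs(ctl)[, "Signature.2"]) / 2))
    expect_error(sampleSpectrum(c(Signature.1 = -0.1, Signature.2 = 1.1),
                                ctl, 10), "negative")
})

test_that("branch channel counts match the mixture by chi-square GOF", {
    tree <- list(list(id = "trunk", parent = NA,
                      ccf = c(primary = 1, relapse = 1), nMut = 5000,
                      sigWeights = c(Signature.2 = 0.3, Signature.6 = 0.7),
                      indelFraction = 0, deletionFraction = 0))
    cfg <- simulationConfig(cloneTree = tree, nNullSites = 0,
                            lostFraction = 0, gapFraction = 0, seed = 21)
    p <- simulatePatient(cfg)
    ctl <- syntheticSignatureCatalog()
    rd <- SummarizedExperiment::rowData(mutations(p))
    counts <- spectrumFromChannels(rd$channel)
    pmix <- as.numeric(probs(ctl)[, c("Signature.2", "Signature.6")] %*%
                       c(0.3, 0.7))
    keep <- pmix > 1e-6
    gof <- suppressWarnings(
        chisq.test(counts[keep], p = pmix[keep] / sum(pmix[keep])))
    expect_gt(gof$p.value, 0.01)
})

test_that("fixtures round-trip losslessly and degenerate patients write", {
    p <- simulatePatient(simulationConfig(seed = 4))
    dir <- withr::local_tempdir()
    paths <- writeFixture(p, dir)
    ms2 <- readMutationTable(paths[["mutations"]],
                             purity(mutations(p)))
    expect_identical(altCounts(ms2), altCounts(mutations(p)))
    expect_identical(depths(ms2), depths(mutations(p)))
    seg2 <- readSegments(paths[["segments_primary"]])
    orig <- segments(p)[segments(p)$sample == "primary"]
    expect_equal(GenomicRanges::start(seg2), GenomicRanges::start(orig))
    expect_equal(seg2$totalCN, orig$totalCN)
    tr2 <- utils::read.delim(paths[["truth"]])
    expect_identical(nrow(tr2), nrow(mutations(p)))
    expect_identical(anyDuplicated(tr2$mutation_id), 0L)

    # empty patient: headers only, still readable
    tree <- list(list(id = "trunk", parent = NA,
                      ccf = c(primary = 1, relapse = 1), nMut = 0,
                      sigWeights = c(Signature.1 = 1)))
    p0 <- simulatePatient(simulationConfig(cloneTree = tree,
                                           nNullSites = 0, seed = 1))
    d0 <- withr::local_tempdir()
    paths0 <- writeFixture(p0, d0)
    ms0 <- readMutationTable(paths0[["mutations"]],
                             purity(mutations(p0)))
    expect_identical(nrow(ms0), 0L)
})
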