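ctl <- syntheticSignatureCatalog()

test_that("combination counts are exact", {
    expect_identical(countCombinations(27, 7), 1285623)
    expect_identical(countCombinations(27, 1), 27)
    # enumeration oracle at K = 4, max 2: all subsets listed explicitly
    subsets <- c(utils::combn(4, 1, simplify = FALSE),
                 utils::combn(4, 2, simplify = FALSE))
    expect_equal(countCombinations(4, 2), length(subsets))
    expect_error(countCombinations(5, 6), "1..K")
})

test_that("a pure spectrum is reconstructed exactly", {
    sp <- 1000 * probs(ctl)[, "Signature.7"]
    fit <- fitExposures(sp, "Signature.7", ctl)
    expect_equal(unname(fit$exposures), 1000, tolerance = 1e-6)
    expect_equal(fit$r, 1, tolerance = 1e-9)
    expect_error(fitExposures(rep(0, 96), "Signature.1", ctl), "all zero")
    expect_error(fitExposures(sp, character(0), ctl), "non-empty")
})

test_that("noise-free mixtures match the grid-search oracle within 1%", {
    pair <- c("Signature.3", "Signature.9")
    sp <- 1000 * as.numeric(probs(ctl)[, pair] %*% c(0.7, 0.3))
    fit <- fitExposures(sp, pair, ctl)
    expect_equal(unname(fit$exposures), c(700, 300), tolerance = 0.01)
    oracle <- gridFit2(sp, probs(ctl)[, pair])
    expect_lt(max(abs(unname(fit$exposures) - unname(oracle))), 10)
    # a single wrong signature scores strictly lower
    wrong <- fitExposures(sp, "Signature.12", ctl)
    expect_lt(wrong$r, fit$r)
})

test_that("exposures sum to the spectrum total within 2%", {
    set.seed(5)
    for (i in 1:5) {
        w <- rgamma(3, 1); w <- w / sum(w)
        names(w) <- sample(signatureNames(ctl), 3)
        sp <- sampleSpectrum(w, ctl, 4000)
        fit <- fitExposures(sp, names(w), ctl)
        expect_lt(abs(sum(fit$exposures) - sum(sp)) / sum(sp), 0.02)
    }
})

test_that("model selection recovers a single generating signature", {
    sp <- sampleSpectrum(c(Signature.2 = 1), ctl, 5000, seed = 6)
    sol <- selectModel(sp, ctl, maxSize = 3)
    expect_true("Signature.2" %in% signatureNames(sol))
    nonExempt <- setdiff(signatureNames(sol),
                         c("Signature.1", "Signature.5", "Signature.2"))
    expect_length(nonExempt, 0L)
    expect_gte(reconstructionR(sol), 0.99)
})

test_that("the 0.02 improvement rule retains the smaller model", {
    # build a spectrum from one signature; adding any second signature
    # cannot improve r by 0.02 once r is already ~1
    sp <- round(3000 * probs(ctl)[, "Signature.11"])
    sol <- selectModel(sp, ctl, maxSize = 2)
    expect_identical(length(signatureNames(sol)), 1L)
    audit <- sol@audit
    expect_true(any(grepl("size 2 rejected", audit$ladder)) ||
                all(is.na(audit$bestRPerSize[2])))
})

test_that("solutions violating the 2%/50-mutation rule are discarded", {
    # 97.5/2.5 mixture at 2000 mutations: the minor signature carries 50
    # mutations > 2% of total? 2.5% of 2000 = 50 -> admissible boundary;
    # at 1.5% (30 mutations) the pair is inadmissible
    spBad <- round(2000 * as.numeric(
        probs(ctl)[, c("Signature.4", "Signature.13")] %*% c(0.985, 0.015)))
    sol <- selectModel(spBad, ctl, maxSize = 2)
    expect_false("Signature.13" %in% setdiff(signatureNames(sol),
                                             c("Signature.1", "Signature.5")))
    # exempt signatures may stay below threshold
    spMix <- round(3000 * as.numeric(
        probs(ctl)[, c("Signature.4", "Signature.1")] %*% c(0.99, 0.01)))
    solMix <- selectModel(spMix, ctl, maxSize = 2)
    expect_true("Signature.4" %in% signatureNames(solMix))
})

test_that("selection is invariant to catalogue column order", {
    sp <- sampleSpectrum(c(Signature.6 = 0.6, Signature.14 = 0.4), ctl,
                         3000, seed = 8)
    shuffled <- SignatureCatalog(probs(ctl)[, sample(27)])
    s1 <- selectModel(sp, ctl, maxSize = 3)
    s2 <- selectModel(sp, shuffled, maxSize = 3)
    expect_identical(signatureNames(s1), signatureNames(s2))
    expect_equal(exposures(s1), exposures(s2), tolerance = 1e-6)
})

test_that("branch refitting recovers per-branch mixtures", {
    tree <- list(
        list(id = "trunk", parent = NA, ccf = c(primary = 1, relapse = 1),
             nMut = 3000,
             sigWeights = c(Signature.1 = 0.3, Signature.3 = 0.7),
             indelFraction = 0, deletionFraction = 0),
        list(id = "small", parent = "trunk",
             ccf = c(primary = 0.4, relapse = 0), nMut = 15,
             sigWeights = c(Signature.2 = 1),
             indelFraction = 0, deletionFraction = 0))
    cfg <- simulationConfig(cloneTree = tree, nNullSites = 0,
                            lostFraction = 0, gapFraction = 0,
                            depthMean = 80, seed = 13)
    p <- simulatePatient(cfg)
    cs <- new("ClusterSet",
              ccf = rbind(c(1, 1), c(0.4, 0)),
              ccfLower = rbind(c(0.9, 0.9), c(0.3, 0)),
              ccfUpper = rbind(c(1, 1), c(0.5, 0.1)),
              sizes = c(3000L, 15L),
              assignments = ifelse(truth(p)$branch_id == "trunk", 1L, 2L),
              memberships = cbind(truth(p)$branch_id == "trunk",
                                  truth(p)$branch_id != "trunk") * 1,
              mutationIds = truth(p)$mutation_id,
              merged = c(FALSE, FALSE), diagnostics = list())
    tr <- buildTree(cs)
    sols <- branchSignatures(tr, mutations(p), ctl, maxSize = 4)
    big <- sols[[which.max(vapply(tr@branchMutations, length, 1L))]]
    expect_s4_class(big, "ExposureSolution")
    expect_true("Signature.3" %in% signatureNames(big))
    e3 <- exposures(big)["Signature.3"] / big@total
    expect_lt(abs(e3 - 0.7), 0.05)
    smallIdx <- which.min(vapply(tr@branchMutations, length, 1L))
    expect_match(sols[[smallIdx]], "skipped")
})

test_that("identical branch spectra give identical solutions", {
    sp <- sampleSpectrum(c(Signature.10 = 1), ctl, 2500, seed = 14)
    s1 <- selectModel(sp, ctl, maxSize = 3)
    s2 <- selectModel(sp, ctl, maxSize = 3)
    expect_identical(signatureNames(s1), signatureNames(s2))
    expect_identical(exposures(s1), exposures(s2))
})
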