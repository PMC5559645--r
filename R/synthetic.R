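#' @include ccf.R io.R
NULL

#' Deterministic synthetic signature catalogue
#'
#' Builds a synthetic stand-in for a consensus 96-channel signature
#' catalogue: `K` sparse, well-separated probability columns over the
#' canonical channels, generated from a fixed internal seed so every call
#' returns the same catalogue. It is *not* the COSMIC catalogue; it exists
#' so that refitting can be exercised and validated against known mixing
#' weights without redistributing reference data.
#'
#' Each signature concentrates mass on a handful of preferred channels
#' (gamma-distributed weights, most mass on ~8 channels), which makes the
#' columns mutually distinguishable — the property refitting relies on.
#'
#' @param K Number of signatures, default 27.
#' @return A [SignatureCatalog-class] with columns
#'   \code{Signature.1..Signature.K}.
#' @export
syntheticSignatureCatalog <- function(K = 27) {
    state <- .Random.seed_exists()
    on.exit(.Random.seed_restore(state))
    set.seed(902137)
    chan <- channelNames()
    P <- vapply(seq_len(K), function(k) {
        w <- stats::rgamma(96, shape = 0.08)
        peaks <- sample.int(96, 8)
        w[peaks] <- w[peaks] + stats::rgamma(8, shape = 3)
        w / sum(w)
    }, numeric(96))
    rownames(P) <- chan
    colnames(P) <- paste0("Signature.", seq_len(K))
    SignatureCatalog(P)
}

.Random.seed_exists <- function() {
    if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(state) {
    if (is.null(state)) {
        if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
}

#' Default two-sample clone tree
#'
#' A trunk clonal in both samples plus one subclone private to each sample,
#' with cancer cell fractions respecting lineage monotonicity. Mutation
#' loads are scaled-down analogues of whole-genome burdens so that tests
#' and examples stay fast; signature mixtures default to three processes
#' with the first signature strongest on the trunk.
#'
#' @param samples Sample names (2-4).
#' @param nTrunk,nPrivate Mutation counts for the trunk and each private
#'   branch.
#' @return A list of branch descriptions usable as
#'   \code{simulationConfig(cloneTree = ...)}.
#' @export
defaultCloneTree <- function(samples = c("primary", "relapse"),
                             nTrunk = 500, nPrivate = 150) {
    stopifnot(length(samples) >= 2, length(samples) <= 4)
    trunkW <- c(Signature.1 = 0.4, Signature.2 = 0.2, Signature.3 = 0.4)
    branchW <- c(Signature.1 = 0.2, Signature.2 = 0.5, Signature.3 = 0.3)
    mk <- function(id, parent, ccf, nMut, w)
        list(id = id, parent = parent,
             ccf = stats::setNames(ccf, samples), nMut = nMut,
             sigWeights = w, indelFraction = 0.1, deletionFraction = 0.5)
    tree <- list(mk("trunk", NA, rep(1, length(samples)), nTrunk, trunkW))
    ccfA <- c(0.6, rep(0, length(samples) - 1))
    ccfB <- c(0, 0.7, rep(0, length(samples) - 2))
    tree <- c(tree, list(mk("primary_private", "trunk", ccfA, nPrivate,
                            branchW),
                         mk("recurrence_private", "trunk", ccfB, nPrivate,
                            branchW)))
    tree
}

#' Simulation configuration
#'
#' Validates and completes a configuration for [simulatePatient()]. The
#' defaults describe the cohort the package targets: 2 samples per patient
#' (a treatment-naive primary and a recurrence), mean whole-genome depth
#' 42x, purities at least 0.7 (histopathology-screened cellularity), a
#' trunk-dominated clone tree, and a sequencing error rate of 1/200.
#'
#' @param samples Sample names, 2-4.
#' @param depthMean Mean sequencing depth (reads), Poisson-distributed per
#'   site with floor 1.
#' @param purity Optional named purities; otherwise drawn uniformly from
#'   `purityRange`.
#' @param purityRange Interval within [0.1, 1].
#' @param cloneTree Branch list (see [defaultCloneTree()]); per-sample CCFs
#'   must be monotone along lineages and 1 on the trunk.
#' @param wgd List `(enabled, tTrue)`: when enabled the genome is
#'   tetraploid and a fraction tTrue/(2 - tTrue) of trunk mutations are
#'   pre-duplication (multiplicity 2).
#' @param errorRate Per-read sequencing error, default 0.005.
#' @param nNullSites Mutation-free sites carrying only error reads, to
#'   exercise presence calling.
#' @param lostFraction,gapFraction Fractions of one chromosome deleted in
#'   the last sample / missing from the first sample's segments, to
#'   exercise QC filtering.
#' @param catalog [SignatureCatalog-class] the spectra are drawn from.
#' @param seed Integer seed.
#' @return A validated config (list).
#' @export
simulationConfig <- function(samples = c("primary", "relapse"),
                             depthMean = 42, purity = NULL,
                             purityRange = c(0.7, 1),
                             cloneTree = defaultCloneTree(samples),
                             wgd = list(enabled = FALSE, tTrue = NA),
                             errorRate = 0.005, nNullSites = 50,
                             lostFraction = 0.02, gapFraction = 0.01,
                             catalog = syntheticSignatureCatalog(),
                             seed = 1) {
    if (length(samples) < 2 || length(samples) > 4)
        stopf("between 2 and 4 samples per patient")
    if (purityRange[1] < 0.1 || purityRange[2] > 1)
        stopf("purity range must lie within [0.1, 1]")
    if (errorRate <= 0 || errorRate >= 1) stopf("error rate must be in (0,1)")
    ids <- vapply(cloneTree, `[[`, "", "id")
    if (anyDuplicated(ids)) stopf("duplicate branch id")
    for (br in cloneTree) {
        if (length(br$ccf) != length(samples))
            stopf("branch %s: one CCF per sample required", br$id)
        if (any(br$ccf < 0 | br$ccf > 1))
            stopf("branch %s: CCFs must lie in [0, 1]", br$id)
        if (is.na(br$parent)) {
            if (any(abs(br$ccf - 1) > 1e-9))
                stopf("trunk branch %s must have CCF 1 in every sample", br$id)
        } else {
            p <- cloneTree[[match(br$parent, ids)]]
            if (is.null(p)) stopf("branch %s: unknown parent %s", br$id, br$parent)
            if (any(br$ccf > p$ccf + 1e-9))
                stopf("branch %s violates CCF monotonicity against parent %s",
                      br$id, br$parent)
        }
        w <- br$sigWeights
        if (any(w < 0)) stopf("branch %s: negative signature weight", br$id)
        if (abs(sum(w) - 1) > 1e-9)
            stopf("branch %s: signature weights must sum to 1", br$id)
        if (!all(names(w) %in% signatureNames(catalog)))
            stopf("branch %s: unknown signature in mixture", br$id)
    }
    if (sum(vapply(cloneTree, function(b) is.na(b$parent), TRUE)) != 1L)
        stopf("exactly one trunk (parent NA) required")
    if (isTRUE(wgd$enabled) && (is.na(wgd$tTrue) || wgd$tTrue < 0 ||
                                wgd$tTrue > 1))
        stopf("WGD timing tTrue must lie in [0, 1]")
    list(samples = samples, depthMean = depthMean, purity = purity,
         purityRange = purityRange, cloneTree = cloneTree, wgd = wgd,
         errorRate = errorRate, nNullSites = nNullSites,
         lostFraction = lostFraction, gapFraction = gapFraction,
         catalog = catalog, seed = seed)
}

#' Draw a 96-channel spectrum from a signature mixture
#'
#' Counts are multinomial from the mixed channel probabilities
#' \code{catalog \%*\% weights}.
#'
#' @param weights Named non-negative weights summing to 1 over catalogue
#'   signatures.
#' @param catalog A [SignatureCatalog-class].
#' @param nMut Number of mutations.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @return Named integer 96-vector summing to `nMut`.
#' @export
sampleSpectrum <- function(weights, catalog, nMut, seed = NULL) {
    if (any(weights < 0)) stopf("signature weights must be non-negative")
    if (abs(sum(weights) - 1) > 1e-9) stopf("weights must sum to 1")
    if (!is.null(seed)) set.seed(seed)
    P <- probs(catalog)[, names(weights), drop = FALSE]
    p <- as.numeric(P %*% weights)
    counts <- if (nMut > 0) as.integer(stats::rmultinom(1, nMut, p))
              else integer(96)
    stats::setNames(counts, channelNames())
}

#' Simulate a multi-sample patient with known ground truth
#'
#' Generates mutations branch by branch on a toy genome (chr1..chr5, 5 Mb
#' each): each mutation draws a generating signature from its branch
#' mixture and a channel from that signature; depth is Poisson around
#' `depthMean` (floor 1); variant reads are Binomial(n, f) with f from
#' [expectedVAF()] given the branch CCF, sample purity, copy number and
#' multiplicity, or Binomial(n, errorRate) where the true VAF is zero
#' (absent branches, deleted regions, null sites). Under WGD the genome is
#' tetraploid and trunk mutations are pre-duplication (multiplicity 2) with
#' probability tTrue / (2 - tTrue).
#'
#' @param config A list from [simulationConfig()].
#' @return A [SyntheticPatient-class]; identical configs (including seed)
#'   give identical output.
#' @export
simulatePatient <- function(config) {
    config <- do.call(simulationConfig, config[setdiff(names(config), "")])
    set.seed(config$seed)
    samples <- config$samples
    S <- length(samples)
    chroms <- paste0("chr", 1:5)
    chromLen <- 5e6

    rho <- config$purity
    if (is.null(rho))
        rho <- stats::setNames(stats::runif(S, config$purityRange[1],
                                            config$purityRange[2]), samples)
    wgdOn <- isTRUE(config$wgd$enabled)
    baseCN <- if (wgdOn) 4L else 2L
    baseMinor <- if (wgdOn) 2L else 1L
    piEarly <- if (wgdOn) config$wgd$tTrue / (2 - config$wgd$tTrue) else 0

    ## --- segments: whole chromosomes at base ploidy; a deleted region on
    ## chr1 in the last sample; a segment gap on chr2 in the first sample
    lostEnd <- round(config$lostFraction * chromLen * length(chroms))
    gapEnd <- round(config$gapFraction * chromLen * length(chroms))
    seg <- list()
    for (s in samples) {
        for (ch in chroms) {
            st <- 0; en <- chromLen
            if (ch == "chr1" && s == samples[S] && lostEnd > 0) {
                seg[[length(seg) + 1L]] <- data.frame(
                    chrom = ch, start = 0, end = lostEnd, total_cn = 0L,
                    minor_cn = 0L, sample = s)
                st <- lostEnd
            }
            if (ch == "chr2" && s == samples[1L] && gapEnd > 0) st <- gapEnd
            seg[[length(seg) + 1L]] <- data.frame(
                chrom = ch, start = st, end = en, total_cn = baseCN,
                minor_cn = baseMinor, sample = s)
        }
    }
    segdf <- do.call(rbind, seg)
    segments <- segmentTable(chrom = segdf$chrom, start = segdf$start,
                             end = segdf$end, totalCN = segdf$total_cn,
                             minorCN = segdf$minor_cn, sample = segdf$sample)

    ## --- mutations per branch
    P <- probs(config$catalog)
    rows <- list()
    for (br in config$cloneTree) {
        n <- br$nMut
        if (n == 0) next
        sig <- sample(names(br$sigWeights), n, replace = TRUE,
                      prob = br$sigWeights)
        channel <- vapply(sig, function(g)
            sample(rownames(P), 1, prob = P[, g]), "")
        isIndel <- stats::runif(n) < (br$indelFraction %||% 0)
        isDel <- isIndel & stats::runif(n) < (br$deletionFraction %||% 0.5)
        class <- ifelse(!isIndel, "substitution",
                        ifelse(isDel, "deletion", "insertion"))
        indelLen <- ifelse(class == "deletion",
                           pmin(1L + stats::rgeom(n, 0.25), 100L),
                           ifelse(class == "insertion",
                                  pmin(1L + stats::rgeom(n, 0.5), 10L), 0L))
        trunkBranch <- is.na(br$parent)
        mult <- ifelse(trunkBranch & wgdOn & stats::runif(n) < piEarly, 2L, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
            branch_id = br$id, signature_id = ifelse(isIndel, NA, sig),
            channel = ifelse(isIndel, NA, channel), class = class,
            indel_length = indelLen, multiplicity = mult,
            stringsAsFactors = FALSE)
    }
    if (config$nNullSites > 0)
        rows[[length(rows) + 1L]] <- data.frame(
            branch_id = "null", signature_id = NA, channel = NA,
            class = "substitution", indel_length = 0L,
            multiplicity = NA_integer_, stringsAsFactors = FALSE)[
                rep(1, config$nNullSites), ]
    mut <- if (length(rows)) do.call(rbind, rows)
           else data.frame(branch_id = character(0),
                           signature_id = character(0),
                           channel = character(0), class = character(0),
                           indel_length = integer(0),
                           multiplicity = integer(0),
                           stringsAsFactors = FALSE)
    N <- nrow(mut)
    rownames(mut) <- NULL

    ## positions uniform over the toy genome
    gpos <- sort(sample.int(chromLen * length(chroms), N))
    mut$chrom <- chroms[(gpos - 1) %/% chromLen + 1]
    mut$pos <- as.integer((gpos - 1) %% chromLen + 1)
    bases <- c("A", "C", "G", "T")
    refFromChannel <- function(chan, class) {
        ifelse(class != "substitution" | is.na(chan), "N",
               substr(chan, 3, 3))
    }
    mut$ref <- refFromChannel(mut$channel, mut$class)
    mut$alt <- ifelse(mut$class == "substitution",
                      ifelse(is.na(mut$channel),
                             "T", substr(mut$channel, 5, 5)),
                      "N")
    mut$ref[mut$class == "substitution" & is.na(mut$channel)] <- "C"
    ## give indels ref/alt strings encoding their length
    isDel <- mut$class == "deletion"
    isIns <- mut$class == "insertion"
    mut$ref[isDel] <- strrep("A", mut$indel_length[isDel] + 1L)
    mut$alt[isDel] <- "A"
    mut$ref[isIns] <- "A"
    mut$alt[isIns] <- strrep("A", mut$indel_length[isIns] + 1L)

    ids <- sprintf("mut%05d", seq_len(N))
    branchCcf <- do.call(rbind, lapply(config$cloneTree, `[[`, "ccf"))
    rownames(branchCcf) <- vapply(config$cloneTree, `[[`, "", "id")
    ccfTruth <- matrix(0, N, S, dimnames = list(ids, samples))
    known <- mut$branch_id != "null"
    ccfTruth[known, ] <- branchCcf[mut$branch_id[known], , drop = FALSE]

    ## per-sample copy number at each site (deleted region aware)
    X <- n <- matrix(0L, N, S, dimnames = list(ids, samples))
    for (s in seq_len(S)) {
        nDepth <- pmax(1L, stats::rpois(N, config$depthMean))
        cnHere <- rep(baseCN, N)
        if (s == S && lostEnd > 0)
            cnHere[mut$chrom == "chr1" & mut$pos <= lostEnd] <- 0L
        mHere <- ifelse(is.na(mut$multiplicity), 1L,
                        pmin(mut$multiplicity, pmax(cnHere, 1L)))
        f <- ifelse(cnHere >= 1 & ccfTruth[, s] > 0,
                    expectedVAF(rho[s], pmax(cnHere, 1), mHere,
                                ccfTruth[, s]),
                    0)
        f0 <- f <= 0
        X[, s] <- stats::rbinom(N, nDepth, ifelse(f0, config$errorRate, f))
        n[, s] <- nDepth
    }

    ms <- MutationSet(chrom = mut$chrom, pos = mut$pos, ref = mut$ref,
                      alt = mut$alt, class = mut$class, X = X, n = n,
                      purity = rho, channel = mut$channel, ids = ids)
    truth <- data.frame(mutation_id = ids, branch_id = mut$branch_id,
                        stringsAsFactors = FALSE)
    for (s in samples) truth[[paste0("true_ccf_", s)]] <- ccfTruth[, s]
    truth$multiplicity <- mut$multiplicity
    truth$signature_id <- mut$signature_id
    truth$indel_length <- mut$indel_length
    methods::new("SyntheticPatient", mutations = ms, segments = segments,
                 truth = truth,
                 config = config[setdiff(names(config), "catalog")])
}

#' Write a synthetic patient as a fixture file set
#'
#' Emits `mutations.tsv`, one `segments_<sample>.tsv` per sample,
#' `purity.tsv` and `truth.tsv` in the package's TSV dialects; the set
#' round-trips losslessly through [readMutationTable()] / [readSegments()].
#'
#' @param patient A [SyntheticPatient-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
writeFixture <- function(patient, dir) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stopf("cannot create directory %s", dir)
    ms <- mutations(patient)
    paths <- c(mutations = file.path(dir, "mutations.tsv"))
    writeMutationTable(ms, paths["mutations"])
    for (s in colnames(ms)) {
        p <- file.path(dir, paste0("segments_", s, ".tsv"))
        writeSegments(segments(patient)[segments(patient)$sample == s], p)
        paths[paste0("segments_", s)] <- p
    }
    paths["purity"] <- file.path(dir, "purity.tsv")
    utils::write.table(data.frame(sample = colnames(ms),
                                  purity = unname(purity(ms))),
                       paths["purity"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["truth"] <- file.path(dir, "truth.tsv")
    utils::write.table(truth(patient), paths["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paths)
}
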