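#' @include dpcluster.R
NULL

#' Binomial presence test for a mutation in one sample
#'
#' A mutation is called present in a sample when its variant reads are
#' unlikely to arise from sequencing error alone: present iff the upper
#' binomial tail P(Binomial(n, errorRate) >= X) is <= 0.05. With the
#' conservative default error rate of 1/200, X = 0 is always absent and an
#' untyped site (n = 0) returns NA (untyped, distinct from absent).
#'
#' @param X Variant reads (vectorised).
#' @param n Depth.
#' @param errorRate Per-read error rate, default 1/200.
#' @param alpha Tail-probability threshold, default 0.05.
#' @return Logical: TRUE present, FALSE absent, NA untyped.
#' @export
#' @examples
#' presenceCall(3, 100)    # TRUE  (tail p ~ 0.0141)
#' presenceCall(1, 200)    # FALSE (tail p ~ 0.633)
presenceCall <- function(X, n, errorRate = 1 / 200, alpha = 0.05) {
    if (errorRate <= 0 || errorRate >= 1)
        stopf("error rate must lie in (0, 1)")
    len <- max(length(X), length(n))
    X <- rep_len(X, len); n <- rep_len(n, len)
    if (any(n < 0)) stopf("depth must be >= 0")
    p <- stats::pbinom(X - 1, n, errorRate, lower.tail = FALSE)
    out <- p <= alpha & X > 0
    out[n == 0] <- NA
    out
}

#' Presence of a structural variant across samples
#'
#' An SV is present in a sample if it was reconstructed there or if 4 or
#' more split reads support the breakpoint.
#'
#' @param splitReads Non-negative split-read counts per sample (named).
#' @param reconstructed Optional logical per sample.
#' @param minSplitReads Threshold, default 4.
#' @return A list: logical `present` per sample, `label`
#'   (\code{"shared"}/\code{"private"}), `privateTo` (sample name or NA),
#'   and `inconsistent` (TRUE when no sample reaches the threshold).
#' @export
svPresence <- function(splitReads, reconstructed = NULL, minSplitReads = 4) {
    if (any(splitReads < 0)) stopf("split-read counts must be >= 0")
    present <- splitReads >= minSplitReads
    if (!is.null(reconstructed)) present <- present | reconstructed
    k <- sum(present)
    list(present = present,
         label = if (k >= 2) "shared" else "private",
         privateTo = if (k == 1) names(splitReads)[present] %||%
             which(present) else NA,
         inconsistent = k == 0)
}

#' Build a rooted tree of clusters by the pigeonhole principle
#'
#' The trunk is the unique cluster with CCF >= 1 - tol in every sample.
#' Cluster A may be ancestral to B only if A's CCF dominates B's in every
#' sample (within tol), and the CCFs of sibling clusters may not sum above
#' their parent's in any sample (within tol). All parent assignments
#' satisfying both constraints are enumerated; they are ranked by total
#' nesting depth and the deepest tree is returned as primary, with the rest
#' in `@alternatives`. Pairs of clusters that dominate each other within
#' tolerance are merged with a warning before enumeration.
#'
#' Mutations are assigned to the branch of their maximum posterior
#' membership cluster; ties go to the more ancestral cluster.
#'
#' @param clusters A [ClusterSet-class].
#' @param tol Dominance tolerance on CCF, default 0.05.
#' @param mutationClasses Optional named character vector (mutation id ->
#'   class) used to tabulate per-branch substitution/indel/SV counts.
#' @return A [PhyloTree-class].
#' @export
buildTree <- function(clusters, tol = 0.05, mutationClasses = NULL) {
    cc <- pmin(ccf(clusters), 1)   # truncate to [0,1] for tree building
    sizes <- clusterSizes(clusters)
    K <- nrow(cc)
    trunk <- which(rowSums(cc >= 1 - tol) == ncol(cc))
    if (length(trunk) == 0L)
        stopf("no clonal cluster: no cluster has CCF >= %.2f in every sample",
              1 - tol)

    ## merge cyclic dominance (mutual within tol)
    dom <- function(a, b) all(cc[a, ] >= cc[b, ] - tol)
    merged <- seq_len(K)
    for (a in seq_len(K)) for (b in seq_len(K)) {
        if (a < b && dom(a, b) && dom(b, a) &&
            !(a %in% trunk && b %in% trunk)) {
            warnf("clusters %d and %d dominate each other within tolerance; merging",
                  a, b)
            merged[merged == b] <- a
        }
    }
    if (length(trunk) > 1L) merged[merged %in% trunk] <- trunk[1L]
    keep <- sort(unique(merged))
    if (length(keep) < K) {
        part <- match(merged, keep)
        newCcf <- t(vapply(keep, function(g) {
            w <- sizes[merged == g]
            colSums(cc[merged == g, , drop = FALSE] * w) / sum(w)
        }, numeric(ncol(cc))))
        cc <- matrix(newCcf, ncol = ncol(cc),
                     dimnames = list(NULL, colnames(ccf(clusters))))
        sizes <- vapply(keep, function(g) sum(sizes[merged == g]), 1L)
        remap <- part
        K <- length(keep)
        trunk <- which(rowSums(cc >= 1 - tol) == ncol(cc))
        if (length(trunk) == 0L) trunk <- which.max(rowSums(cc))
    } else remap <- seq_len(K)
    if (length(trunk) != 1L)
        stopf("expected exactly one clonal cluster, found %d", length(trunk))

    ## enumerate parent assignments consistent with dominance + pigeonhole
    candidates <- lapply(seq_len(K), function(b) {
        if (b == trunk) return(NA_integer_)
        ok <- setdiff(which(vapply(seq_len(K), function(a)
            a != b && dom(a, b), TRUE)), b)
        if (!length(ok)) ok <- trunk   # dominance noise: attach to trunk
        ok
    })
    grids <- expand.grid(candidates, KEEP.OUT.ATTRS = FALSE)
    valid <- list()
    for (r in seq_len(nrow(grids))) {
        par <- as.integer(unlist(grids[r, ]))
        if (!isAcyclic(par, trunk)) next
        if (!pigeonholeOK(par, cc, tol)) next
        valid[[length(valid) + 1L]] <- par
    }
    if (!length(valid))
        stopf("no tree satisfies the pigeonhole constraints at tolerance %.2f",
              tol)
    depth <- vapply(valid, function(par) sum(nodeDepths(par, trunk)), 0)
    o <- order(-depth)
    primary <- valid[[o[1L]]]
    alternatives <- valid[o[-1L]]

    ## branch assignment by maximum posterior membership, ancestral ties
    memb <- memberships(clusters)
    ancRank <- rowSums(ccf(clusters))   # larger = more ancestral
    branch <- integer(nrow(memb))
    for (i in seq_len(nrow(memb))) {
        mx <- max(memb[i, ])
        tied <- which(memb[i, ] >= mx - 1e-9)
        branch[i] <- tied[which.max(ancRank[tied])]
    }
    branch <- remap[branch]
    ids <- clusters@mutationIds
    branchMut <- lapply(seq_len(K), function(k) ids[branch == k])

    classes <- c("substitution", "insertion", "deletion", "SV")
    bc <- matrix(0L, K, length(classes), dimnames = list(NULL, classes))
    if (!is.null(mutationClasses)) {
        for (k in seq_len(K)) {
            tab <- table(factor(mutationClasses[branchMut[[k]]],
                                levels = classes))
            bc[k, ] <- as.integer(tab)
        }
    } else bc[, "substitution"] <- vapply(branchMut, length, 1L)

    methods::new("PhyloTree",
                 clusterIds = paste0("cluster", seq_len(K)),
                 parent = primary, ccf = cc,
                 branchMutations = branchMut, branchCounts = bc,
                 alternatives = alternatives, tol = tol)
}

isAcyclic <- function(parent, root) {
    for (i in seq_along(parent)) {
        seen <- integer(0)
        j <- i
        while (!is.na(parent[j])) {
            if (j %in% seen) return(FALSE)
            seen <- c(seen, j)
            j <- parent[j]
        }
    }
    TRUE
}

pigeonholeOK <- function(parent, cc, tol) {
    for (p in seq_along(parent)) {
        kids <- which(!is.na(parent) & parent == p)
        if (length(kids) >= 2L &&
            any(colSums(cc[kids, , drop = FALSE]) > cc[p, ] + tol))
            return(FALSE)
    }
    TRUE
}

nodeDepths <- function(parent, root) {
    vapply(seq_along(parent), function(i) {
        d <- 0L; j <- i
        while (!is.na(parent[j])) { d <- d + 1L; j <- parent[j] }
        d
    }, 1L)
}

treeRootIndex <- function(tree) which(is.na(tree@parent))

## substitution count of a branch, optionally restricted to an id set
branchSubs <- function(tree, k, restrict = NULL) {
    ids <- tree@branchMutations[[k]]
    if (!is.null(restrict)) ids <- intersect(ids, restrict)
    if (is.null(restrict)) tree@branchCounts[k, "substitution"]
    else length(ids)
}

## per-branch presence in a sample from cluster CCFs
branchPresent <- function(tree, sample, ccfCutoff = 0.05) {
    tree@ccf[, sample] > ccfCutoff
}

#' Molecular time of recurrence divergence
#'
#' The fraction of the primary tumor's molecular time at which the
#' recurrence-seeding clone diverges: substitutions on the shared lineage
#' from the root to the divergence node, divided by substitutions on the
#' primary's root-to-tip lineage (the most-mutated primary leaf lineage).
#' Restrict `cnConstantIds` to substitutions in regions with identical copy
#' number across all samples, which keeps branch lengths comparable.
#'
#' @param tree A [PhyloTree-class].
#' @param primarySample,recurrenceSample Sample names (columns of the
#'   cluster CCF matrix).
#' @param cnConstantIds Optional mutation ids in copy-number-constant
#'   regions; branch lengths count only these.
#' @param ccfCutoff CCF below which a branch is absent from a sample.
#' @return Fraction in [0, 1].
#' @export
divergenceFraction <- function(tree, primarySample, recurrenceSample,
                               cnConstantIds = NULL, ccfCutoff = 0.05) {
    root <- treeRootIndex(tree)
    inPrim <- branchPresent(tree, primarySample, ccfCutoff)
    inRec <- branchPresent(tree, recurrenceSample, ccfCutoff)
    len <- vapply(seq_along(tree@clusterIds), function(k)
        branchSubs(tree, k, cnConstantIds), numeric(1))

    ## divergence node: deepest node present in both primary and recurrence
    shared <- which(inPrim & inRec)
    if (!length(shared)) stopf("samples share no lineage")
    depth <- nodeDepths(tree@parent, root)
    divNode <- shared[which.max(depth[shared])]
    sharedLen <- lineageLength(tree, divNode, len)

    ## primary lineage: root-to-tip path maximising substitutions among
    ## primary-present nodes (the longest primary lineage; see vignette)
    primNodes <- which(inPrim)
    if (!length(primNodes)) stopf("primary lineage is empty")
    primLen <- max(vapply(primNodes, function(k)
        lineageLength(tree, k, len, restrict = primNodes), numeric(1)))
    if (primLen == 0) stopf("primary lineage carries no substitutions")
    min(sharedLen / primLen, 1)
}

lineageLength <- function(tree, node, len, restrict = NULL) {
    total <- 0
    j <- node
    repeat {
        if (is.null(restrict) || j %in% restrict) total <- total + len[j]
        if (is.na(tree@parent[j])) break
        j <- tree@parent[j]
    }
    total
}

#' Recurrence-specific mutation excess
#'
#' The substitution load in branches private to the recurrence minus the
#' load in branches private to the primary, as a percentage of all
#' substitutions identified in the primary tumor. Negative when the primary
#' carries the larger private load.
#'
#' @inheritParams divergenceFraction
#' @return Percentage (may be negative).
#' @export
recurrenceExcess <- function(tree, primarySample, recurrenceSample,
                             ccfCutoff = 0.05) {
    inPrim <- branchPresent(tree, primarySample, ccfCutoff)
    inRec <- branchPresent(tree, recurrenceSample, ccfCutoff)
    len <- tree@branchCounts[, "substitution"]
    nPrimTotal <- sum(len[inPrim])
    if (nPrimTotal == 0) stopf("no substitutions identified in the primary")
    100 * (sum(len[inRec & !inPrim]) - sum(len[inPrim & !inRec])) / nPrimTotal
}

#' Deletion enrichment at relapse
#'
#' Compares relapse-private indels with trunk indels in two 2x2 tables:
#' deletions versus insertions, and deletions >= 5 bp versus shorter.
#' p-values are two-sided Fisher exact tests; odds ratios are sample odds
#' ratios with a Haldane correction of 0.5 added to every cell when any
#' cell is zero (flagged in the result).
#'
#' @param relapseIndels,trunkIndels Data frames with columns `class`
#'   (\code{insertion}/\code{deletion}) and `length` (bp).
#' @param longCutoff Length defining a long deletion, default 5.
#' @return A list with elements `deletionVsInsertion` and
#'   `longVsShortDeletion`, each carrying `table`, `or`, `p`,
#'   `haldane`.
#' @export
deletionEnrichment <- function(relapseIndels, trunkIndels, longCutoff = 5) {
    if (nrow(relapseIndels) == 0L || nrow(trunkIndels) == 0L)
        stopf("indel sets must be non-empty")
    tab1 <- rbind(relapse = c(deletion = sum(relapseIndels$class == "deletion"),
                              insertion = sum(relapseIndels$class == "insertion")),
                  trunk = c(sum(trunkIndels$class == "deletion"),
                            sum(trunkIndels$class == "insertion")))
    rdel <- relapseIndels[relapseIndels$class == "deletion", ]
    tdel <- trunkIndels[trunkIndels$class == "deletion", ]
    tab2 <- rbind(relapse = c(long = sum(rdel$length >= longCutoff),
                              short = sum(rdel$length < longCutoff)),
                  trunk = c(sum(tdel$length >= longCutoff),
                            sum(tdel$length < longCutoff)))
    list(deletionVsInsertion = fisher2x2(tab1),
         longVsShortDeletion = fisher2x2(tab2))
}

fisher2x2 <- function(tab) {
    haldane <- any(tab == 0)
    t2 <- if (haldane) tab + 0.5 else tab
    or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
    p <- stats::fisher.test(tab)$p.value
    list(table = tab, or = or, p = p, haldane = haldane)
}

#' @describeIn exportNewick Newick string with branch lengths equal to
#'   per-branch substitution counts, written via \pkg{ape}.
#' @param file Optional path; when given the string is also written there.
#' @export
setMethod("exportNewick", "PhyloTree", function(x, file = NULL, ...) {
    phy <- asPhylo(x)
    txt <- ape::write.tree(phy)
    if (!is.null(file)) writeLines(txt, file)
    invisible(txt)
})

#' Convert a PhyloTree to an ape "phylo" object
#'
#' Internal nodes with mutations are represented with zero-length leaf
#' stubs so branch lengths (substitution counts) are preserved.
#'
#' @param x A [PhyloTree-class].
#' @return An \pkg{ape} \code{phylo} object.
#' @export
asPhylo <- function(x) {
    nwk <- buildNewick(x, treeRootIndex(x),
                       x@branchCounts[, "substitution"])
    ape::read.tree(text = nwk)
}

buildNewick <- function(x, node, len) {
    kids <- which(!is.na(x@parent) & x@parent == node)
    lab <- x@clusterIds[node]
    inner <- if (length(kids)) {
        paste0("(", paste(c(vapply(kids, function(k)
            buildNewick(x, k, len), ""),
            sprintf("%s_tip:0", lab)), collapse = ","), ")")
    } else ""
    core <- if (nzchar(inner)) paste0(inner, lab) else lab
    if (is.na(x@parent[node])) {
        # a bare single-node tree still needs a parenthesised newick form
        if (!nzchar(inner)) paste0("(", core, ":", len[node], ");")
        else paste0(core, ":", len[node], ";")
    } else paste0(core, ":", len[node])
}

#' Per-branch statistics table
#'
#' @param tree A [PhyloTree-class].
#' @return A data.frame with one row per branch: cluster id, parent,
#'   per-class mutation counts and per-sample CCFs.
#' @export
branchStats <- function(tree) {
    par <- ifelse(is.na(tree@parent), NA_character_,
                  tree@clusterIds[tree@parent])
    data.frame(cluster = tree@clusterIds, parent = par,
               tree@branchCounts, round(tree@ccf, 4),
               check.names = FALSE, stringsAsFactors = FALSE)
}
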