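#' @include phylogeny.R
NULL

#' Read a cancer-gene metadata table
#'
#' TSV with columns `gene`, `role` (\code{oncogene}/\code{TSG}/\code{both})
#' and optional hotspot records: `hotspot_pos`, `hotspot_count` (prior
#' somatic reports at the locus), `canonical` (canonical oncogenic hotspot
#' flag), `splice_site` (splice-site hotspot flag). One row per
#' gene-hotspot; genes without hotspots appear once with empty hotspot
#' fields.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
readCancerGenes <- function(path) {
    if (!file.exists(path)) stopf("no such file: %s", path)
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("gene", "role")
    if (!all(need %in% colnames(df)))
        stopf("cancer-gene table must contain columns %s",
              paste(need, collapse = ", "))
    if (!all(df$role %in% c("oncogene", "TSG", "both")))
        stopf("role must be oncogene, TSG or both")
    for (col in c("hotspot_pos", "hotspot_count"))
        if (!col %in% colnames(df)) df[[col]] <- NA_integer_
    for (col in c("canonical", "splice_site"))
        if (!col %in% colnames(df)) df[[col]] <- FALSE
    if (any(df$hotspot_count < 0, na.rm = TRUE))
        stopf("hotspot counts must be >= 0")
    df
}

consequenceClasses <- c("missense", "nonsense", "frameshift",
                        "essential_splice", "inframe_deletion", "silent",
                        "synonymous", "other")

#' Rule-based driver annotation of a coding mutation
#'
#' Applies four oncogenicity categories in order of precedence, returning
#' the first match:
#' \enumerate{
#'   \item a canonical oncogenic mutation at a recurrent hotspot;
#'   \item a non-synonymous substitution or in-frame deletion in an
#'     oncogene at a locus with >= 3 prior somatic reports;
#'   \item in a tumor suppressor, a truncating (nonsense), frameshift or
#'     essential splice variant, or any variant at a hotspot with >= 2
#'     prior somatic reports;
#'   \item a silent mutation at a known recurrent splice-site hotspot.
#' }
#' Mutations in genes absent from the cancer-gene table return `NULL`.
#'
#' @param gene Gene symbol.
#' @param pos Genomic position (matched against hotspot records).
#' @param consequence One of `r paste(consequenceClasses, collapse=", ")`.
#' @param geneTable Data frame from [readCancerGenes()].
#' @return A list (gene, category, evidence) or `NULL`.
#' @export
annotateDriver <- function(gene, pos, consequence, geneTable) {
    if (!consequence %in% consequenceClasses)
        stopf("unknown consequence class '%s'", consequence)
    rec <- geneTable[geneTable$gene == gene, , drop = FALSE]
    if (nrow(rec) == 0L) return(NULL)
    role <- rec$role[1L]
    hot <- rec[!is.na(rec$hotspot_pos) & rec$hotspot_pos == pos, ,
               drop = FALSE]
    silent <- consequence %in% c("silent", "synonymous")
    truncating <- consequence %in% c("nonsense", "frameshift",
                                     "essential_splice")
    coding <- consequence %in% c("missense", "inframe_deletion")

    ## category 1: canonical hotspot
    if (nrow(hot) && any(hot$canonical) && !silent)
        return(list(gene = gene, category = 1L,
                    evidence = "canonical hotspot"))
    ## category 2: oncogene locus with >= 3 prior somatic reports
    if (role %in% c("oncogene", "both") && coding && nrow(hot) &&
        any(hot$hotspot_count >= 3, na.rm = TRUE))
        return(list(gene = gene, category = 2L,
                    evidence = sprintf("oncogene hotspot, %d prior reports",
                                       max(hot$hotspot_count))))
    ## category 3: TSG truncating, or TSG hotspot with >= 2 reports
    if (role %in% c("TSG", "both") &&
        (truncating ||
         (!silent && nrow(hot) && any(hot$hotspot_count >= 2, na.rm = TRUE))))
        return(list(gene = gene, category = 3L,
                    evidence = if (truncating) "TSG truncating"
                               else "TSG hotspot"))
    ## category 4: silent at a splice-site hotspot
    if (silent && nrow(hot) && any(hot$splice_site))
        return(list(gene = gene, category = 4L,
                    evidence = "silent at splice-site hotspot"))
    NULL
}

#' Copy-number driver calls
#'
#' Whole-genome mode: a gene is amplified when an overlapping segment's
#' total copy number exceeds twice the genome-average ploidy, and
#' homozygously deleted when total copy number is 0. Targeted mode: a gene
#' is amplified when its mean logR exceeds 1 (about 6 alleles in a diploid
#' genome at 50\% cellularity); calls of heterogeneous amplification across
#' related samples are flagged for manual review rather than auto-called.
#'
#' @param geneRegions \linkS4class{GRanges} of gene footprints with a
#'   `gene` metadata column (wgs mode).
#' @param segments Segment \linkS4class{GRanges} of one sample (wgs mode).
#' @param ploidy Genome-average ploidy (wgs mode).
#' @param mode \code{"wgs"} or \code{"targeted"}.
#' @param logR Named numeric of gene-level mean logR (targeted mode).
#' @param logRCI Optional two-column matrix of 95\% CI bounds, reported but
#'   not used in the call.
#' @return A data.frame: gene, call, value, reviewFlag.
#' @export
callCopyNumberDrivers <- function(geneRegions = NULL, segments = NULL,
                                  ploidy = NULL,
                                  mode = c("wgs", "targeted"),
                                  logR = NULL, logRCI = NULL) {
    mode <- match.arg(mode)
    if (mode == "wgs") {
        if (is.null(ploidy)) stopf("wgs mode requires a ploidy estimate")
        if (is.null(geneRegions) || is.null(segments))
            stopf("wgs mode requires gene regions and segments")
        ov <- GenomicRanges::findOverlaps(geneRegions, segments)
        out <- list()
        for (h in seq_along(ov)) {
            g <- geneRegions$gene[S4Vectors::queryHits(ov)[h]]
            cn <- segments$totalCN[S4Vectors::subjectHits(ov)[h]]
            if (cn > 2 * ploidy)
                out[[length(out) + 1L]] <- data.frame(
                    gene = g, call = "amplification", value = cn,
                    reviewFlag = FALSE)
            else if (cn == 0)
                out[[length(out) + 1L]] <- data.frame(
                    gene = g, call = "homozygous-deletion", value = cn,
                    reviewFlag = FALSE)
        }
        if (!length(out))
            return(data.frame(gene = character(0), call = character(0),
                              value = numeric(0), reviewFlag = logical(0)))
        unique(do.call(rbind, out))
    } else {
        if (is.null(logR)) stopf("targeted mode requires gene-level logR")
        amp <- logR > 1
        df <- data.frame(gene = names(logR),
                         call = ifelse(amp, "amplification", "none"),
                         value = unname(logR),
                         reviewFlag = amp,   # heterogeneity needs review
                         stringsAsFactors = FALSE)
        if (!is.null(logRCI)) {
            df$ci_low <- logRCI[, 1]; df$ci_high <- logRCI[, 2]
        }
        df[df$call != "none", , drop = FALSE]
    }
}

#' Gene-level enrichment of driver mutations between cohorts
#'
#' For every gene, a two-sided Fisher exact test on mutated/unmutated
#' counts in the relapse versus primary cohorts, with Benjamini-Hochberg
#' correction across genes; genes with q < `qCutoff` are flagged.
#'
#' @param relapseCounts,primaryCounts Data frames with columns `gene`,
#'   `mutated`, `total`.
#' @param qCutoff Significance threshold on q, default 0.1.
#' @return A data.frame: gene, or (sample odds ratio), p, q, significant.
#' @export
enrichmentTest <- function(relapseCounts, primaryCounts, qCutoff = 0.1) {
    genes <- union(relapseCounts$gene, primaryCounts$gene)
    get <- function(df, g) {
        r <- df[df$gene == g, , drop = FALSE]
        if (nrow(r) == 0L) c(0, NA) else c(r$mutated[1L], r$total[1L])
    }
    res <- lapply(genes, function(g) {
        r <- get(relapseCounts, g); p <- get(primaryCounts, g)
        if (is.na(r[2]) || is.na(p[2]) || r[2] <= 0 || p[2] <= 0)
            stopf("gene %s: cohort totals must be positive", g)
        if (r[1] > r[2] || p[1] > p[2])
            stopf("gene %s: mutated count exceeds total", g)
        tab <- rbind(relapse = c(r[1], r[2] - r[1]),
                     primary = c(p[1], p[2] - p[1]))
        ft <- stats::fisher.test(tab)
        t2 <- if (any(tab == 0)) tab + 0.5 else tab
        data.frame(gene = g,
                   or = (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1]),
                   p = ft$p.value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$q < qCutoff
    out[order(out$p), ]
}

#' Timing of driver mutations between primary and recurrence
#'
#' For each driver gene in a patient with a matched primary: `early` when
#' the identical mutation is present in both primary and recurrence,
#' `late` when detected in the recurrence only (requiring the primary site
#' to be typed, n > 0, and absent by [presenceCall()], so coverage dropouts
#' cannot masquerade as late drivers), and `both-different` when the two
#' lesions carry different mutations of the same gene.
#'
#' @param calls Data frame of driver point mutations with columns
#'   `mutation_id`, `gene`, `X_primary`, `n_primary`, `X_recurrence`,
#'   `n_recurrence`.
#' @param errorRate Passed to [presenceCall()].
#' @return A data.frame: gene, timing, detail; or timing withheld (NA with
#'   reason) when the primary is untyped.
#' @export
driverTiming <- function(calls, errorRate = 1 / 200) {
    if (nrow(calls) == 0L)
        return(data.frame(gene = character(0), timing = character(0),
                          detail = character(0)))
    calls$inPrimary <- presenceCall(calls$X_primary, calls$n_primary,
                                    errorRate)
    calls$inRecurrence <- presenceCall(calls$X_recurrence,
                                       calls$n_recurrence, errorRate)
    res <- lapply(split(calls, calls$gene), function(g) {
        if (all(is.na(g$inPrimary)))
            return(data.frame(gene = g$gene[1L], timing = NA_character_,
                              detail = "primary untyped"))
        shared <- g$inPrimary %in% TRUE & g$inRecurrence %in% TRUE
        primOnly <- g$inPrimary %in% TRUE & !(g$inRecurrence %in% TRUE)
        recOnly <- g$inRecurrence %in% TRUE & g$inPrimary %in% FALSE
        timing <- if (any(shared)) "early"
            else if (any(recOnly) && any(primOnly)) "both-different"
            else if (any(recOnly)) "late"
            else NA_character_
        data.frame(gene = g$gene[1L], timing = timing,
                   detail = paste0(sum(shared), " shared, ",
                                   sum(primOnly), " primary-only, ",
                                   sum(recOnly), " recurrence-only"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
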