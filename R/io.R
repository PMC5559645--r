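#' @include MutationSet.R
NULL

## TSV dialect headers (documented contract):
##   mutation table: chrom, pos, ref, alt [, class, gene, consequence,
##     channel], then one "X_<sample>" and one "n_<sample>" column per sample.
##   segment table: chrom, start, end, total_cn, minor_cn
##     [, subclonal_fraction], sample  -- start/end 0-based half-open (BED).
##   purity table: sample, purity.
## Mutation positions are 1-based (VCF convention); the 0-based half-open
## segment coordinates are converted to 1-based closed GRanges on read and
## back on write, so all in-memory overlap arithmetic uses one convention.

#' Read a multi-sample somatic mutation table
#'
#' Two dialects are supported: a TSV with per-sample variant-read columns
#' \code{X_<sample>} and depth columns \code{n_<sample>}, and a VCF subset
#' carrying per-sample \code{AD} and \code{DP} FORMAT fields (only the first
#' alternate allele is used). Missing depth is treated as 0 (site untyped).
#'
#' @param path File path.
#' @param purity Named numeric vector of per-sample purities.
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @return A [MutationSet-class] with samples in file order.
#' @export
readMutationTable <- function(path, purity, dialect = c("tsv", "vcf")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stopf("no such file: %s", path)
    if (dialect == "tsv") readMutationTSV(path, purity)
    else readMutationVCF(path, purity)
}

readMutationTSV <- function(path, purity) {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(df)))
        stopf("mutation TSV must contain columns %s", paste(need, collapse = ", "))
    xcols <- grep("^X_", colnames(df), value = TRUE)
    ncols <- grep("^n_", colnames(df), value = TRUE)
    samples <- sub("^X_", "", xcols)
    if (!setequal(samples, sub("^n_", "", ncols)))
        stopf("X_/n_ sample columns do not match")
    ncols <- paste0("n_", samples)   # preserve X-column sample order
    X <- as.matrix(df[, xcols, drop = FALSE]); colnames(X) <- samples
    n <- as.matrix(df[, ncols, drop = FALSE]); colnames(n) <- samples
    n[is.na(n)] <- 0L
    X[is.na(X)] <- 0L
    bad <- which(rowSums(X > n) > 0)
    if (length(bad))
        stopf("variant reads exceed depth at row %d of %s", bad[1L], path)
    MutationSet(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
                class = if ("class" %in% colnames(df)) df$class else NULL,
                X = X, n = n, purity = purity,
                gene = if ("gene" %in% colnames(df)) df$gene else NULL,
                consequence = if ("consequence" %in% colnames(df))
                    df$consequence else NULL,
                channel = if ("channel" %in% colnames(df)) df$channel else NULL,
                ids = if ("mutation_id" %in% colnames(df))
                    df$mutation_id else NULL)
}

readMutationVCF <- function(path, purity) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
    if (!all(c("AD", "DP") %in% fmt))
        stopf("VCF dialect requires per-sample AD and DP FORMAT fields")
    ad <- vcfR::extract.gt(v, element = "AD")
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    # AD = ref,alt[,...]; take the first alternate allele only
    X <- apply(ad, 2, function(col)
        as.integer(vapply(strsplit(col, ","), function(z)
            if (length(z) >= 2L) z[2L] else "0", "")))
    n <- dp
    n[is.na(n)] <- 0
    X[is.na(X)] <- 0L
    alt1 <- vapply(strsplit(fix[, "ALT"], ","), `[`, "", 1L)
    MutationSet(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                ref = fix[, "REF"], alt = alt1,
                X = X, n = matrix(as.integer(n), nrow = nrow(X),
                                  dimnames = dimnames(X)),
                purity = purity)
}

#' Write a MutationSet to the TSV dialect
#'
#' @param x A [MutationSet-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeMutationTable <- function(x, path) {
    rr <- SummarizedExperiment::rowRanges(x)
    rd <- SummarizedExperiment::rowData(x)
    df <- data.frame(mutation_id = rownames(x),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     ref = rd$ref, alt = rd$alt, class = rd$class,
                     stringsAsFactors = FALSE)
    for (opt in c("gene", "consequence", "channel"))
        if (opt %in% colnames(rd)) df[[opt]] <- rd[[opt]]
    X <- altCounts(x); n <- depths(x)
    for (s in colnames(x)) df[[paste0("X_", s)]] <- X[, s]
    for (s in colnames(x)) df[[paste0("n_", s)]] <- n[, s]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' Expects a BED-like TSV with 0-based half-open intervals and columns
#' \code{chrom}, \code{start}, \code{end}, \code{total_cn}, \code{minor_cn},
#' optional \code{subclonal_fraction}, and \code{sample}. Intervals are
#' converted to 1-based closed coordinates in the returned
#' \linkS4class{GRanges}, so a segment \code{(chr1, 0, 1000)} covers
#' mutation positions 1..1000. Overlapping segments within one sample are
#' rejected.
#'
#' @param path File path.
#' @return A \linkS4class{GRanges} with metadata columns \code{totalCN},
#'   \code{minorCN}, \code{subclonalFraction}, \code{sample}.
#' @export
readSegments <- function(path) {
    if (!file.exists(path)) stopf("no such file: %s", path)
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "total_cn", "minor_cn", "sample")
    if (!all(need %in% colnames(df)))
        stopf("segment TSV must contain columns %s", paste(need, collapse = ", "))
    if (!"subclonal_fraction" %in% colnames(df))
        df$subclonal_fraction <- rep(1, nrow(df))
    segmentTable(chrom = df$chrom, start = df$start, end = df$end,
                 totalCN = df$total_cn, minorCN = df$minor_cn,
                 subclonalFraction = df$subclonal_fraction,
                 sample = df$sample)
}

#' Build a validated segment GRanges from 0-based half-open intervals
#'
#' @param chrom,start,end Interval coordinates, BED convention.
#' @param totalCN,minorCN Total and minor allele copy number.
#' @param subclonalFraction Fraction of tumor cells carrying the segment
#'   state, in (0, 1].
#' @param sample Sample identifier per segment.
#' @return A \linkS4class{GRanges} (1-based closed).
#' @export
segmentTable <- function(chrom, start, end, totalCN, minorCN,
                         subclonalFraction = 1, sample) {
    n <- length(start)
    if (n == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            totalCN = integer(0), minorCN = integer(0),
            subclonalFraction = numeric(0), sample = character(0))
        return(gr)
    }
    if (any(start >= end)) stopf("segment start must be < end")
    if (any(totalCN < 0)) stopf("total copy number must be >= 0")
    if (any(minorCN > totalCN - minorCN))
        stopf("minor copy number must not exceed total - minor")
    if (any(subclonalFraction <= 0 | subclonalFraction > 1))
        stopf("subclonal fraction must lie in (0, 1]")
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start + 1L, end = end),
        totalCN = as.integer(totalCN), minorCN = as.integer(minorCN),
        subclonalFraction = subclonalFraction,
        sample = rep_len(as.character(sample), n))
    for (s in unique(gr$sample)) {
        gs <- gr[gr$sample == s]
        ov <- GenomicRanges::findOverlaps(gs, drop.self = TRUE,
                                          drop.redundant = TRUE)
        if (length(ov))
            stopf("overlapping segments in sample %s: %s and %s", s,
                  as.character(gs[S4Vectors::queryHits(ov)[1L]]),
                  as.character(gs[S4Vectors::subjectHits(ov)[1L]]))
    }
    gr
}

#' Write segments back to the BED-like TSV dialect
#'
#' @param segments A segment \linkS4class{GRanges} from [readSegments()] or
#'   [segmentTable()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeSegments <- function(segments, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(segments)),
        start = GenomicRanges::start(segments) - 1L,
        end = GenomicRanges::end(segments),
        total_cn = segments$totalCN, minor_cn = segments$minorCN,
        subclonal_fraction = segments$subclonalFraction,
        sample = segments$sample, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Construct a SignatureCatalog
#'
#' @param probs 96 x K matrix of channel probabilities with rownames either
#'   in canonical COSMIC order or carrying canonical channel labels (rows are
#'   reordered by label).
#' @return A [SignatureCatalog-class].
#' @export
SignatureCatalog <- function(probs) {
    probs <- as.matrix(probs)
    if (nrow(probs) != 96L)
        stopf("catalogue must have 96 channels, got %d", nrow(probs))
    chan <- channelNames()
    if (is.null(rownames(probs))) rownames(probs) <- chan
    if (!setequal(rownames(probs), chan))
        stopf("channel labels do not match the COSMIC 96-channel convention")
    probs <- probs[chan, , drop = FALSE]
    if (is.null(colnames(probs)))
        colnames(probs) <- paste0("Signature.", seq_len(ncol(probs)))
    cs <- colSums(probs)
    if (any(abs(cs - 1) > 1e-3))
        stopf("signature column '%s' sums to %.4f, not 1",
              colnames(probs)[which.max(abs(cs - 1))], cs[which.max(abs(cs - 1))])
    probs <- sweep(probs, 2, cs, "/")   # exact normalisation within tolerance
    methods::new("SignatureCatalog", probs = probs)
}

#' Read a 96-channel signature catalogue
#'
#' Expects a TSV whose first column (named \code{channel}) carries the 96
#' trinucleotide channel labels and whose remaining columns are signature
#' probability vectors. Rows may appear in any order; they are restored to
#' the canonical COSMIC order by label.
#'
#' @param path File path.
#' @return A [SignatureCatalog-class].
#' @export
readSignatureCatalog <- function(path) {
    if (!file.exists(path)) stopf("no such file: %s", path)
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (colnames(df)[1L] != "channel")
        stopf("first column of a signature catalogue must be 'channel'")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$channel
    SignatureCatalog(m)
}

#' Write a signature catalogue
#'
#' @param catalog A [SignatureCatalog-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeSignatureCatalog <- function(catalog, path) {
    df <- data.frame(channel = rownames(probs(catalog)),
                     probs(catalog), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
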