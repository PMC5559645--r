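genes <- toyGeneTable()

test_that("driver categories follow rule precedence", {
    # canonical hotspot -> category 1
    c1 <- annotateDriver("ONC1", 1000, "missense", genes)
    expect_identical(c1$category, 1L)
    # oncogene locus with >= 3 prior reports -> category 2
    c2 <- annotateDriver("ONC1", 2000, "missense", genes)
    expect_identical(c2$category, 2L)
    # TSG truncating -> category 3
    expect_identical(annotateDriver("TSG1", 9999, "nonsense",
                                    genes)$category, 3L)
    expect_identical(annotateDriver("TSG1", 9999, "frameshift",
                                    genes)$category, 3L)
    # TSG hotspot with >= 2 reports, non-truncating -> category 3
    expect_identical(annotateDriver("TSG1", 3000, "missense",
                                    genes)$category, 3L)
    # silent at a splice-site hotspot -> category 4
    expect_identical(annotateDriver("TSG1", 4000, "silent",
                                    genes)$category, 4L)
    # silent away from any splice hotspot -> none
    expect_null(annotateDriver("TSG1", 123, "silent", genes))
    # gene not in the table -> none
    expect_null(annotateDriver("NOTAGENE", 1, "nonsense", genes))
    expect_error(annotateDriver("TSG1", 1, "weird", genes),
                 "unknown consequence")
})

test_that("every annotated mutation receives at most one category", {
    set.seed(10)
    cons <- c("missense", "nonsense", "frameshift", "silent",
              "inframe_deletion", "essential_splice")
    for (i in 1:50) {
        g <- sample(c(genes$gene, "OTHER"), 1)
        pos <- sample(c(genes$hotspot_pos, 1, 99), 1)
        call <- annotateDriver(g, pos, sample(cons, 1), genes)
        expect_true(is.null(call) ||
                    (length(call$category) == 1L &&
                     call$category %in% 1:4))
    }
})

test_that("copy-number driver calls use the ploidy and logR thresholds", {
    gr <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                 IRanges::IRanges(c(100, 100),
                                                  c(200, 200)),
                                 gene = c("ONC1", "TSG1"))
    seg <- segmentTable(chrom = c("chr1", "chr2"), start = c(0, 0),
                        end = c(1000, 1000), totalCN = c(9L, 0L),
                        minorCN = c(2L, 0L), sample = "P")
    calls <- callCopyNumberDrivers(gr, seg, ploidy = 4, mode = "wgs")
    expect_identical(calls$call[calls$gene == "ONC1"], "amplification")
    expect_identical(calls$call[calls$gene == "TSG1"],
                     "homozygous-deletion")
    # CN 8 at ploidy 4 is NOT amplified (strictly more than twice)
    seg2 <- segmentTable(chrom = "chr1", start = 0, end = 1000,
                         totalCN = 8L, minorCN = 2L, sample = "P")
    expect_identical(nrow(callCopyNumberDrivers(gr[1], seg2, ploidy = 4,
                                                mode = "wgs")), 0L)
    expect_error(callCopyNumberDrivers(gr, seg, mode = "wgs"), "ploidy")
    # targeted mode: logR > 1 amplifies, 0.9 does not; calls are flagged
    t1 <- callCopyNumberDrivers(mode = "targeted",
                                logR = c(ERBB2 = 1.4, MYC = 0.9))
    expect_identical(t1$gene, "ERBB2")
    expect_true(all(t1$reviewFlag))
})

test_that("enrichment tests match the hypergeometric oracle", {
    rel <- data.frame(gene = c("G1", "G2", "G3"),
                      mutated = c(20L, 5L, 8L), total = 163L)
    pri <- data.frame(gene = c("G1", "G2", "G3"),
                      mutated = c(20L, 30L, 34L), total = 705L)
    res <- enrichmentTest(rel, pri)
    for (g in res$gene) {
        a <- rel$mutated[rel$gene == g]
        c_ <- pri$mutated[pri$gene == g]
        oracle <- fisherOracle(a, 163 - a, c_, 705 - c_)
        expect_equal(res$p[res$gene == g], oracle, tolerance = 1e-12)
    }
    # q-values are BH and monotone in rank-ordered p
    o <- order(res$p)
    expect_true(all(diff(res$q[o]) >= -1e-12))
    expect_equal(res$q, p.adjust(res$p, "BH"), tolerance = 1e-12)
    expect_error(enrichmentTest(
        data.frame(gene = "G", mutated = 10L, total = 5L),
        data.frame(gene = "G", mutated = 1L, total = 10L)), "exceeds total")
})

test_that("identical frequencies are not flagged and single gene has q = p", {
    rel <- data.frame(gene = "G1", mutated = 10L, total = 100L)
    pri <- data.frame(gene = "G1", mutated = 50L, total = 500L)
    res <- enrichmentTest(rel, pri)
    expect_equal(res$or, 1)
    expect_equal(res$p, 1)
    expect_false(res$significant)
    expect_identical(res$q, res$p)   # BH identity at m = 1
})

test_that("fisher oracle agrees with fisher.test across small tables", {
    for (a in c(0, 1, 3, 8)) for (b in c(2, 5, 12)) {
        for (c_ in c(0, 4, 9)) for (d in c(1, 6, 15)) {
            expect_equal(fisher.test(rbind(c(a, b), c(c_, d)))$p.value,
                         fisherOracle(a, b, c_, d), tolerance = 1e-12)
        }
    }
})

test_that("driver timing distinguishes early, late and both-different", {
    calls <- data.frame(
        mutation_id = c("m1", "m2", "m3", "m4", "m5"),
        gene = c("TP53", "PIK3CA", "ARID1A", "ARID1A", "JAK2"),
        X_primary = c(20L, 0L, 15L, 0L, 0L),
        n_primary = c(50L, 60L, 40L, 55L, 0L),
        X_recurrence = c(25L, 30L, 0L, 20L, 18L),
        n_recurrence = c(55L, 50L, 45L, 50L, 40L))
    res <- driverTiming(calls)
    expect_identical(res$timing[res$gene == "TP53"], "early")
    expect_identical(res$timing[res$gene == "PIK3CA"], "late")
    expect_identical(res$timing[res$gene == "ARID1A"], "both-different")
    # primary untyped: withheld with reason
    expect_true(is.na(res$timing[res$gene == "JAK2"]))
    expect_identical(res$detail[res$gene == "JAK2"], "primary untyped")
})

test_that("cancer-gene tables read and validate", {
    path <- withr::local_tempfile()
    utils::write.table(genes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tbl <- readCancerGenes(path)
    expect_identical(tbl$gene, genes$gene)
    bad <- genes
    bad$role[1] <- "mystery"
    utils::write.table(bad, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(readCancerGenes(path), "role")
})
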