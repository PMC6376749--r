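# two genes on chr1: geneA exons [0,100)+[200,300), geneB exon [1000,1200)
two_gene_models <- function(snps) {
    bed <- write_tmp(c(
        paste("chr1", 0, 300, "geneA", 0, "+", 0, 300, 0, 2,
              "100,100,", "0,200,", sep = "\t"),
        paste("chr1", 1000, 1200, "geneB", 0, "-", 1000, 1200, 0, 1,
              "200,", "0,", sep = "\t")), ".bed")
    readGeneModels(bed, snps)
}

test_that("site qualification reads 'either allele' as the maximum", {
    cfg <- expressionFilterConfig()
    expect_true(siteQualifies(3, 0, cfg))
    expect_false(siteQualifies(2, 2, cfg))
    expect_false(siteQualifies(0, 0, cfg))
    cfg_sum <- expressionFilterConfig(siteRule = "sum")
    expect_true(siteQualifies(2, 2, cfg_sum))
})

test_that("the consistency statistic matches closed-form cases", {
    expect_equal(stdem(c(0.5, 0.5, 0.5)), 0)
    expect_equal(stdem(c(1, 0)), 0.5)
    expect_equal(stdem(c(1, 0.8, 1)), 0.06666667, tolerance = 1e-6)
    expect_true(is.na(stdem(0.9)))
    # invariant under reordering and allele swap
    f <- c(0.9, 0.4, 0.7, 0.55)
    expect_equal(stdem(f), stdem(rev(f)))
    expect_equal(stdem(f), stdem(1 - f))
})

test_that("gene sums aggregate exonic sites and flag uncovered genes", {
    snps <- data.frame(chrom = "chr1", pos = c(10, 50, 250, 1100),
                       maternal_base = "A", paternal_base = "G")
    gm <- two_gene_models(snps)
    x <- AllelicCounts("s", counts_df("chr1", c(10, 50, 250),
                                      c(5, 4, 6), c(0, 1, 0)),
                       c(chr1 = 1e6))
    sums <- geneAllelicCounts(x, gm)
    a <- sums[sums$gene_id == "geneA", ]
    expect_equal(a$mat_count, 15)
    expect_equal(a$pat_count, 1)
    expect_equal(a$total, 16)
    expect_equal(a$stdem, 0.06666667, tolerance = 1e-6)
    b <- sums[sums$gene_id == "geneB", ]
    expect_equal(b$total, 0)
})

test_that("gene calls apply the coverage, consistency and bias gates", {
    snps <- data.frame(chrom = "chr1", pos = c(10, 50, 250, 1100),
                       maternal_base = "A", paternal_base = "G")
    gm <- two_gene_models(snps)
    x <- AllelicCounts("s", counts_df("chr1", c(10, 50, 250),
                                      c(5, 4, 6), c(0, 1, 0)),
                       c(chr1 = 1e6))
    calls <- callGenes(x, gm)
    a <- calls[calls$gene_id == "geneA", ]
    expect_equal(a$status, "PASS")
    expect_equal(a$bias, "MATERNAL_BIASED")     # ratio 0.9375 > 0.80
    expect_equal(a$ratio_mat, 15 / 16)
    b <- calls[calls$gene_id == "geneB", ]
    expect_equal(b$status, "LOW_COVERAGE")
    expect_equal(b$bias, "NO_CALL")

    # a total of exactly 9 does not pass the > 9 gate
    x9 <- AllelicCounts("s", counts_df("chr1", 10, 9, 0),
                        c(chr1 = 1e6))
    expect_equal(callGenes(x9, gm)$status[1], "LOW_COVERAGE")
    x10 <- AllelicCounts("s", counts_df("chr1", 10, 10, 0),
                         c(chr1 = 1e6))
    expect_equal(callGenes(x10, gm)$status[1], "PASS")

    # opposite monoallelic sites -> STDEM 0.5 -> inconsistent
    xin <- AllelicCounts("s", counts_df("chr1", c(10, 50),
                                        c(10, 0), c(0, 10)),
                         c(chr1 = 1e6))
    ci <- callGenes(xin, gm)
    expect_equal(ci$status[ci$gene_id == "geneA"], "INCONSISTENT")

    # ratio of exactly 0.80 is biallelic; strictly above is biased
    x80 <- AllelicCounts("s", counts_df("chr1", 10, 16, 4),
                         c(chr1 = 1e6))
    expect_equal(callGenes(x80, gm)$bias[1], "BIALLELIC")
    x81 <- AllelicCounts("s", counts_df("chr1", 10, 17, 4),
                         c(chr1 = 1e6))
    expect_equal(callGenes(x81, gm)$bias[1], "MATERNAL_BIASED")

    # a gene with no exonic SNPs is not informative
    gm0 <- two_gene_models(data.frame(chrom = "chr1", pos = 1100,
                                      maternal_base = "A",
                                      paternal_base = "G"))
    c0 <- callGenes(x, gm0)
    expect_equal(c0$status[c0$gene_id == "geneA"], "NOT_INFORMATIVE")
})

test_that("bias classes mirror under the allele swap", {
    snps <- data.frame(chrom = "chr1", pos = c(10, 50),
                       maternal_base = "A", paternal_base = "G")
    gm <- two_gene_models(snps)
    set.seed(17)
    for (i in 1:50) {
        mat <- sample(0:30, 2); pat <- sample(0:30, 2)
        x <- AllelicCounts("s", counts_df("chr1", c(10, 50), mat, pat),
                           c(chr1 = 1e6))
        xs <- AllelicCounts("s", counts_df("chr1", c(10, 50), pat, mat),
                            c(chr1 = 1e6))
        ca <- callGenes(x, gm); cb <- callGenes(xs, gm)
        a <- ca[ca$gene_id == "geneA", ]; b <- cb[cb$gene_id == "geneA", ]
        expect_equal(a$status, b$status)
        swap <- c(MATERNAL_BIASED = "PATERNAL_BIASED",
                  PATERNAL_BIASED = "MATERNAL_BIASED",
                  BIALLELIC = "BIALLELIC", NO_CALL = "NO_CALL")
        expect_equal(unname(swap[a$bias]), b$bias)
    }
})

test_that("heterozygous restriction keeps only fully contained genes", {
    snps <- data.frame(chrom = "chr1",
                       pos = c(70.0005e6, 59.9995e6, 80e6),
                       maternal_base = "A", paternal_base = "G")
    bed <- write_tmp(c(
        bed_line("chr1", 70e6, 70.001e6, "inside", "+", 1000, 0),
        bed_line("chr1", 59.999e6, 60.002e6, "straddle", "+", 3000, 0)),
        ".bed")
    gm <- readGeneModels(bed, snps)
    x <- counts_from_labels(c(rep("MAT_HOM", 60), rep("HET", 40)))
    map <- genotypeSample(x, genotyperConfig(binSizeMb = 1))
    calls <- data.frame(gene_id = c("inside", "straddle"),
                        status = "PASS",
                        bias = "BIALLELIC", stringsAsFactors = FALSE)
    r <- restrictToHet(calls, gm, map)
    expect_equal(r$status[r$gene_id == "inside"], "PASS")
    expect_equal(r$status[r$gene_id == "straddle"], "NOT_INFORMATIVE")
    # no map (fully heterozygous F1 sample): unchanged
    expect_identical(restrictToHet(calls, gm, NULL), calls)
})

test_that("cohort filter enforces per-class coverage in every sample", {
    mk <- function(tot) data.frame(gene_id = "g", total = tot,
                                   stringsAsFactors = FALSE)
    cfg <- expressionFilterConfig()
    expect_equal(cohortFilter(list(mk(41), mk(100), mk(201)),
                              c("cellline", "cellline", "embryonic"),
                              cfg), "g")
    expect_equal(length(cohortFilter(list(mk(41), mk(100), mk(200)),
                                     c("cellline", "cellline",
                                       "embryonic"), cfg)), 0)
    expect_equal(length(cohortFilter(list(mk(40), mk(100), mk(201)),
                                     c("cellline", "cellline",
                                       "embryonic"), cfg)), 0)
    # absent from one sample -> excluded
    absent <- data.frame(gene_id = "other", total = 500)
    expect_equal(length(cohortFilter(list(mk(100), absent),
                                     c("cellline", "cellline"), cfg)), 0)
})

test_that("interval aggregation matches gene-style summation", {
    x <- AllelicCounts("s", counts_df("chr1", c(1e6, 4.9e6),
                                      c(7, 13), c(3, 17)),
                       c(chr1 = 10e6))
    iv <- data.frame(chrom = "chr1", start = c(0, 6e6, 0),
                     end = c(5e6, 7e6, 10e6))
    agg <- aggregateIntervals(x, iv)
    expect_equal(agg$mat_count, c(20, 0, 20))
    expect_equal(agg$ratio_mat, c(0.5, NA, 0.5))
    # whole-chromosome interval equals the chromosome totals
    expect_equal(agg$total[3],
                 sum(countsTable(x)$mat_count + countsTable(x)$pat_count))
})

test_that("passing-gene maternal ratios are unbiased on simulated data", {
    cl <- c(chr1 = 30e6)
    snps <- makeSnpMap(cl, 1 / 520, seed = 8)
    gm <- makeGeneModels(snps, cl, nGenes = 50, xChrom = NULL, seed = 8)
    truth <- gm$truth
    truth@segments <- truthSegments(f1Genotype(cl))
    st <- cellStateConfig(depth = 100, overdispersion = 0)
    ef <- expectedMatFraction(truth, st)
    errs <- c(); vars <- c()
    for (r in 1:10) {
        s <- simulateSample(snps, gm$genes, truth, st, "u", seed = 100 + r)
        calls <- callGenes(s, gm$genes)
        m <- match(calls$gene_id, ef$gene_id)
        ok <- calls$status == "PASS" & calls$total >= 50
        errs <- c(errs, calls$ratio_mat[ok] - ef$f_expected[m][ok])
        f <- ef$f_expected[m][ok]
        vars <- c(vars, f * (1 - f) / calls$total[ok])
    }
    mc_se <- sqrt(sum(vars)) / length(errs)
    expect_lt(abs(mean(errs)), 3 * mc_se + 1e-12)
})
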