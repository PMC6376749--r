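cfg1 <- genotyperConfig(binSizeMb = 1, mode = "rna")
cfg5 <- genotyperConfig(binSizeMb = 5)

test_that("binning sums counts per half-open bin and conserves totals", {
    x <- AllelicCounts("s", counts_df("chr1", c(1e6, 4.9e6, 5e6),
                                      c(7, 13, 2), c(3, 17, 0)),
                       c(chr1 = 20e6))
    b <- binCounts(x, 5)
    expect_equal(nrow(b), 4)          # every bin present
    expect_equal(b$mat_count[1], 20)  # sites at 1 and 4.9 MB
    expect_equal(b$pat_count[1], 20)
    expect_equal(b$pct_mat[1], 50)
    expect_equal(b$total[2], 2)       # site at exactly 5 MB -> bin 1
    expect_equal(sum(b$total),
                 sum(countsTable(x)$mat_count + countsTable(x)$pat_count))
    # empty chromosome -> all-zero bins
    y <- AllelicCounts("s", counts_df(character(0), numeric(0),
                                      numeric(0), numeric(0)),
                       c(chr1 = 10e6))
    expect_true(all(binCounts(y, 5)$total == 0))
})

test_that("trailing moving average matches the hand-traced series", {
    pct <- c(90, 90, 50, 50, 50, 50)
    x <- AllelicCounts("s",
                       counts_df("chr1", (0:5) * 5e6 + 100,
                                 pct, 100 - pct),
                       c(chr1 = 30e6))
    b <- smoothBins(binCounts(x, 5), cfg5)
    expect_equal(b$pct_smoothed,
                 c(90, 90, 230 / 3, 70, 60, 50))
    # constant series unchanged; first bin equals itself
    x2 <- AllelicCounts("s", counts_df("chr1", (0:3) * 5e6 + 1,
                                       rep(60, 4), rep(40, 4)),
                       c(chr1 = 20e6))
    b2 <- smoothBins(binCounts(x2, 5), cfg5)
    expect_equal(b2$pct_smoothed, rep(60, 4))
})

test_that("moving average skips non-qualifying bins", {
    # middle bin below the 5 MB coverage gate: excluded from windows
    x <- AllelicCounts("s",
                       counts_df("chr1", (0:2) * 5e6 + 1,
                                 c(90, 10, 50), c(10, 10, 50)),
                       c(chr1 = 15e6))
    b <- smoothBins(binCounts(x, 5), cfg5)
    expect_true(is.na(b$pct_smoothed[2]))
    expect_equal(b$pct_smoothed[3], (90 + 50) / 2)
})

test_that("bin classification applies the printed boundaries per resolution", {
    mk <- function(total, pct, cfg) {
        b <- data.frame(chrom = "c", bin = 0, start = 0, end = 1,
                        mat_count = total * pct / 100,
                        pat_count = total * (1 - pct / 100),
                        total = total, pct_mat = pct)
        classifyBins(b, cfg)$label
    }
    # 5 MB: <=40 insufficient; 31 / 78.5 boundaries
    expect_equal(mk(100, 60, cfg5), "HET")
    expect_equal(mk(40, 60, cfg5), "INSUFFICIENT")
    expect_equal(mk(41, 60, cfg5), "HET")
    expect_equal(mk(100, 30.9, cfg5), "PAT_HOM")
    expect_equal(mk(100, 31, cfg5), "HET")
    expect_equal(mk(100, 78.5, cfg5), "MAT_HOM")
    expect_equal(mk(100, 80, cfg5), "MAT_HOM")
    # 1 MB RNA: >10 included; 15 / 85 boundaries
    expect_equal(mk(20, 80, cfg1), "HET")
    expect_equal(mk(10, 80, cfg1), "INSUFFICIENT")
    expect_equal(mk(11, 85, cfg1), "MAT_HOM")
    expect_equal(mk(11, 14.9, cfg1), "PAT_HOM")
    # 1 MB DNA: >15 included
    cfgd <- genotyperConfig(binSizeMb = 1, mode = "dna")
    expect_equal(mk(15, 50, cfgd), "INSUFFICIENT")
    expect_equal(mk(16, 50, cfgd), "HET")
})

test_that("proximal genotype rules fire in order", {
    expect_equal(assignProximalGenotype(
        c("MAT_HOM", "MAT_HOM", "MAT_HOM", "MAT_HOM", "HET"), cfg1),
        "MAT_HOM")                              # 4/5 = 80%
    expect_equal(assignProximalGenotype(
        c("PAT_HOM", "HET", "PAT_HOM", "HET", "PAT_HOM", "HET",
          "PAT_HOM", "HET", "PAT_HOM", "PAT_HOM"), cfg1),
        "PAT_HOM")                              # 6/10 = 60%
    expect_equal(assignProximalGenotype(rep("HET", 6), cfg1), "HET")
    expect_equal(suppressWarnings(assignProximalGenotype(
        rep("HET", 5), cfg1)), "UNASSIGNED")    # needs > 5 consecutive
    # INSUFFICIENT bins are skipped from counting
    expect_equal(assignProximalGenotype(
        c("MAT_HOM", "INSUFFICIENT", "MAT_HOM", "MAT_HOM",
          "INSUFFICIENT", "MAT_HOM", "HET"), cfg1),
        "MAT_HOM")
    expect_warning(assignProximalGenotype(rep("INSUFFICIENT", 10), cfg1),
                   "fewer")
})

test_that("breakpoints match hand-traced examples", {
    x <- counts_from_labels(c(rep("MAT_HOM", 10), rep("HET", 20)))
    map <- genotypeSample(x, cfg1)
    expect_equal(genotypeBreakpoints(map)$pos, 10e6)
    expect_equal(genotypeSegments(map)$label, c("MAT_HOM", "HET"))
    expect_equal(genotypeSegments(map)$start, c(0, 10e6))
    expect_equal(genotypeSegments(map)$end, c(10e6, 30e6))

    x2 <- counts_from_labels(rep("HET", 30))
    expect_equal(nrow(genotypeBreakpoints(genotypeSample(x2, cfg1))), 0)

    # 10 MB heterozygous island with equal flanks is discarded ...
    x3 <- counts_from_labels(c(rep("MAT_HOM", 10), rep("HET", 10),
                               rep("MAT_HOM", 10)))
    m3 <- genotypeSample(x3, cfg1)
    expect_equal(genotypeSegments(m3)$label, "MAT_HOM")
    expect_equal(nrow(genotypeBreakpoints(m3)), 0)
    # ... a 16 MB island is retained
    x4 <- counts_from_labels(c(rep("MAT_HOM", 10), rep("HET", 16),
                               rep("MAT_HOM", 10)))
    expect_equal(genotypeSegments(genotypeSample(x4, cfg1))$label,
                 c("MAT_HOM", "HET", "MAT_HOM"))
})

test_that("segmentation agrees with the brute-force oracle", {
    # exhaustive over all 3^7 classified sequences of length 7
    labs <- c("MAT_HOM", "HET", "PAT_HOM")
    grid <- expand.grid(rep(list(labs), 7), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
        lab <- unlist(grid[i, ], use.names = FALSE)
        o <- oracle_segment(lab, cfg1)
        p <- pkg_segment_bins(lab, cfg1)
        ol <- o$labels; ol[is.na(ol)] <- "UNASSIGNED"
        expect_identical(ol, p$labels)
        expect_identical(as.integer(o$breakpoints),
                         as.integer(p$breakpoints))
    }
    # random longer sequences with insufficient bins mixed in
    set.seed(77)
    for (i in 1:300) {
        lab <- random_label_seq(sample(5:40, 1))
        o <- oracle_segment(lab, cfg1)
        p <- pkg_segment_bins(lab, cfg1)
        ol <- o$labels; ol[is.na(ol)] <- "UNASSIGNED"
        expect_identical(ol, p$labels)
        expect_identical(as.integer(o$breakpoints),
                         as.integer(p$breakpoints))
    }
})

test_that("allele swap mirrors labels at 1 MB but not at 5 MB", {
    set.seed(5)
    swap_map <- c(MAT_HOM = "PAT_HOM", PAT_HOM = "MAT_HOM",
                  HET = "HET", INSUFFICIENT = "INSUFFICIENT")
    mirrored_1mb <- TRUE
    mirrored_5mb <- TRUE
    for (i in 1:300) {
        tot <- sample(11:200, 1)
        mat <- sample(0:tot, 1)
        pct <- 100 * mat / tot
        if (pct %in% c(15, 85, 31, 78.5)) next  # boundary ties documented
        b <- data.frame(chrom = "c", bin = 0, start = 0, end = 1,
                        mat_count = mat, pat_count = tot - mat,
                        total = tot, pct_mat = pct)
        bs <- b; bs$mat_count <- b$pat_count; bs$pat_count <- b$mat_count
        bs$pct_mat <- 100 - pct
        l1 <- classifyBins(b, cfg1)$label
        l1s <- classifyBins(bs, cfg1)$label
        if (l1s != unname(swap_map[l1])) mirrored_1mb <- FALSE
        if (tot > 40) {
            b5 <- b; b5$pct_smoothed <- b$pct_mat
            b5s <- bs; b5s$pct_smoothed <- bs$pct_mat
            l5 <- classifyBins(b5, cfg5)$label
            l5s <- classifyBins(b5s, cfg5)$label
            if (l5s != unname(swap_map[l5])) mirrored_5mb <- FALSE
        }
    }
    expect_true(mirrored_1mb)
    # the 31 / 78.5 boundaries are asymmetric by construction
    expect_false(mirrored_5mb)
})

test_that("adding coverage never demotes a classified bin", {
    set.seed(9)
    for (i in 1:100) {
        tot <- sample(1:60, 1)
        mat <- sample(0:tot, 1)
        b <- data.frame(chrom = "c", bin = 0, start = 0, end = 1,
                        mat_count = mat, pat_count = tot - mat,
                        total = tot, pct_mat = 100 * mat / tot)
        lab <- classifyBins(b, cfg1)$label
        b2 <- b
        b2$mat_count <- b$mat_count + 5
        b2$total <- b2$mat_count + b2$pat_count
        b2$pct_mat <- 100 * b2$mat_count / b2$total
        lab2 <- classifyBins(b2, cfg1)$label
        if (lab != "INSUFFICIENT") expect_false(lab2 == "INSUFFICIENT")
    }
})

test_that("heterozygous regions exclude unassigned chromosomes", {
    x <- counts_from_labels(c(rep("MAT_HOM", 10), rep("HET", 20)))
    map <- genotypeSample(x, cfg1)
    het <- heterozygousRegions(map)
    expect_equal(het$start, 10e6)
    expect_equal(het$end, 30e6)

    x2 <- counts_from_labels(rep("INSUFFICIENT", 30))
    map2 <- genotypeSample(x2, cfg1)
    expect_message(het2 <- heterozygousRegions(map2), "unassigned")
    expect_equal(nrow(het2), 0)
})

test_that("breakpoint accuracy scoring follows its definitions", {
    x <- counts_from_labels(c(rep("MAT_HOM", 10), rep("HET", 20)))
    map <- genotypeSample(x, cfg1)
    acc <- compareGenotypes(map, map)
    expect_equal(acc$exact_fraction, 1)
    expect_equal(acc$mean_abs_error_mb, 0)

    truth <- new("SimTruth",
                 segments = data.frame(chrom = "chr1", start = c(0, 10e6),
                                       end = c(10e6, 30e6),
                                       state = c("HOM_MAT", "HET")),
                 crossovers = data.frame(chrom = "chr1", pos = 12e6),
                 genes = data.frame(),
                 chromLengths = c(chr1 = 30e6))
    acc2 <- compareGenotypes(map, truth)   # called 10 MB vs true 12 MB
    expect_equal(acc2$n_matched, 1)
    expect_equal(acc2$n_exact, 0)
    expect_equal(acc2$mean_abs_error_mb, 2)

    # a spurious extra called breakpoint stays unmatched
    truth0 <- new("SimTruth",
                  segments = truth@segments,
                  crossovers = data.frame(chrom = character(0),
                                          pos = numeric(0)),
                  genes = data.frame(), chromLengths = c(chr1 = 30e6))
    acc3 <- compareGenotypes(map, truth0)
    expect_equal(acc3$n_called, 1)
    expect_equal(acc3$n_matched, 0)
})

test_that("fertilized profiles genotype heterozygous; imbalance is flagged", {
    # clean F1: one heterozygous segment per chromosome
    cl <- c(chr1 = 60e6)
    snps <- makeSnpMap(cl, 1e-4, seed = 31)
    truth <- f1Genotype(cl)
    cov <- simulateAllelicCoverage(snps, truth, 60, 1, seed = 31)
    map <- genotypeSample(cov, cfg1)
    expect_equal(genotypeSegments(map)$label, "HET")
    expect_false(any(imbalanceTable(map)$flagged))

    # 2:1 allelic ratio (trisomy-like): heterozygous but flagged
    n <- 30
    x <- AllelicCounts("tri",
                       counts_df("chr1", (0:(n - 1)) * 1e6 + 5,
                                 rep(20, n), rep(10, n)),
                       c(chr1 = n * 1e6))
    m2 <- genotypeSample(x, cfg1)
    expect_equal(genotypeSegments(m2)$label, "HET")
    expect_true(imbalanceTable(m2)$flagged)
})

test_that("true crossovers away from chromosome ends are recovered", {
    # crossovers < ~5 MB from either end cannot satisfy the published
    # run-length rules; condition on the recoverable configuration
    set.seed(123)
    cl <- c(chr1 = 100e6)
    n_ok <- 0; n_tot <- 0; spurious <- 0
    for (r in 1:40) {
        snps <- makeSnpMap(cl, 1e-4, seed = 1000 + r)
        truth <- simulatePgaGenotype(cl, crossoverModel(c(1, 3)),
                                     seed = 2000 + r)
        xo <- truthCrossovers(truth)$pos
        if (any(xo < 6e6 | xo > 94e6)) next
        cov <- simulateAllelicCoverage(snps, truth, 50, 1,
                                       seed = 3000 + r)
        acc <- compareGenotypes(genotypeSample(cov, cfg1), truth)
        n_tot <- n_tot + 1
        if (acc$n_matched == acc$n_true) n_ok <- n_ok + 1
        spurious <- spurious + max(0, acc$n_called - acc$n_true)
    }
    expect_gt(n_tot, 15)
    expect_gte(n_ok / n_tot, 0.95)
    expect_equal(spurious, 0)
})
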