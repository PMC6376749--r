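#' Does a site qualify for the per-gene consistency statistic?
#'
#' A site is included in the within-gene consistency calculation when it
#' has a coverage of at least `minSiteCov` from either allele — read as
#' `max(mat, pat) >= minSiteCov` (`siteRule = "max"`, the default) or as
#' `mat + pat >= minSiteCov` (`siteRule = "sum"`).
#'
#' @param matCount,patCount allelic counts at the site (vectorised).
#' @param config an [expressionFilterConfig()] list.
#' @return logical vector.
#' @export
siteQualifies <- function(matCount, patCount,
                          config = expressionFilterConfig()) {
    if (config$siteRule == "max")
        pmax(matCount, patCount) >= config$minSiteCov
    else
        (matCount + patCount) >= config$minSiteCov
}

#' Standard error of the mean of per-site maternal fractions
#'
#' Sample standard deviation (n - 1 denominator) of the per-site
#' maternal fractions divided by the square root of the number of
#' sites.  Not applicable (returns `NA`) for fewer than two sites.
#'
#' @param fractions numeric vector of per-site maternal fractions.
#' @return the standard error, or `NA_real_` for < 2 sites.
#' @export
stdem <- function(fractions) {
    n <- length(fractions)
    if (n < 2) return(NA_real_)
    sd(fractions) / sqrt(n)
}

#' Sum allelic counts over the exonic SNP sites of each gene
#'
#' @param x an [AllelicCounts-class] object.
#' @param genes a [GeneModels-class] object.
#' @param config an [expressionFilterConfig()] list (site gating).
#' @return `data.frame` with one row per gene: `gene_id`, `mat_count`,
#'   `pat_count`, `total`, `n_sites` (covered sites), `n_qual_sites`,
#'   `stdem`, `shared_sites` (TRUE when a site is shared with another
#'   gene and therefore double-counted).
#' @export
geneAllelicCounts <- function(x, genes,
                              config = expressionFilterConfig()) {
    df <- countsTable(x)
    st <- siteTable(genes)
    g <- geneTable(genes)
    key <- paste(df$chrom, df$pos)
    skey <- paste(st$chrom, st$pos)
    shared_key <- skey[duplicated(skey)]
    m <- match(skey, key)
    st$mat <- ifelse(is.na(m), 0, df$mat_count[m])
    st$pat <- ifelse(is.na(m), 0, df$pat_count[m])
    st$qual <- siteQualifies(st$mat, st$pat, config)
    if (config$siteGateGeneSums) {
        st$mat[!st$qual] <- 0
        st$pat[!st$qual] <- 0
    }
    split_idx <- split(seq_len(nrow(st)), st$gene_id)
    out <- data.frame(gene_id = g$gene_id,
                      mat_count = 0, pat_count = 0, total = 0,
                      n_sites = 0L, n_qual_sites = 0L,
                      stdem = NA_real_, shared_sites = FALSE,
                      stringsAsFactors = FALSE)
    rownames(out) <- out$gene_id
    for (gid in names(split_idx)) {
        idx <- split_idx[[gid]]
        mat <- st$mat[idx]; pat <- st$pat[idx]
        out[gid, "mat_count"] <- sum(mat)
        out[gid, "pat_count"] <- sum(pat)
        covered <- (mat + pat) > 0
        out[gid, "n_sites"] <- sum(covered)
        q <- st$qual[idx]
        out[gid, "n_qual_sites"] <- sum(q)
        if (sum(q) >= 2) {
            fr <- mat[q] / (mat[q] + pat[q])
            out[gid, "stdem"] <- stdem(fr)
        }
        out[gid, "shared_sites"] <-
            any(paste(st$chrom[idx], st$pos[idx]) %in% shared_key)
    }
    out$total <- out$mat_count + out$pat_count
    if (any(out$shared_sites))
        message(sum(out$shared_sites),
                " gene(s) share exonic SNP sites with another gene; ",
                "shared sites are double-counted")
    rownames(out) <- NULL
    out
}

#' Call gene-level allelic bias
#'
#' Applies the gene-level filters to the summed counts: genes with a
#' total of at most `minGeneCounts` are `LOW_COVERAGE`; genes whose
#' per-site consistency statistic exceeds `maxStdem` are `INCONSISTENT`
#' (bypassed for single-site genes); genes without exonic SNP sites are
#' `NOT_INFORMATIVE`.  Passing genes are classified by the maternal
#' ratio: strictly above `biasThreshold` maternally biased, strictly
#' below `1 - biasThreshold` paternally biased, otherwise biallelic
#' (a ratio of exactly the threshold is biallelic).
#'
#' @param x an [AllelicCounts-class] object (or a precomputed
#'   [geneAllelicCounts()] table via `sums`).
#' @param genes a [GeneModels-class] object.
#' @param config an [expressionFilterConfig()] list.
#' @param sums optional precomputed output of [geneAllelicCounts()].
#' @return `data.frame` per gene: the count columns plus `ratio_mat`,
#'   `status` in `PASS`, `LOW_COVERAGE`, `INCONSISTENT`,
#'   `NOT_INFORMATIVE`, and `bias` in `MATERNAL_BIASED`,
#'   `PATERNAL_BIASED`, `BIALLELIC`, `NO_CALL`.
#' @export
callGenes <- function(x, genes, config = expressionFilterConfig(),
                      sums = NULL) {
    if (is.null(sums)) sums <- geneAllelicCounts(x, genes, config)
    g <- geneTable(genes)
    informative <- g$informative[match(sums$gene_id, g$gene_id)]
    sums$ratio_mat <- ifelse(sums$total > 0,
                             sums$mat_count / sums$total, NA_real_)
    status <- rep("PASS", nrow(sums))
    status[!informative] <- "NOT_INFORMATIVE"
    status[informative & sums$total <= config$minGeneCounts] <-
        "LOW_COVERAGE"
    inc <- informative & sums$total > config$minGeneCounts &
        !is.na(sums$stdem) & sums$stdem > config$maxStdem
    status[inc] <- "INCONSISTENT"
    bias <- rep("NO_CALL", nrow(sums))
    p <- status == "PASS"
    bias[p & sums$ratio_mat > config$biasThreshold] <- "MATERNAL_BIASED"
    bias[p & sums$ratio_mat < 1 - config$biasThreshold] <-
        "PATERNAL_BIASED"
    bias[p & bias == "NO_CALL"] <- "BIALLELIC"
    sums$status <- status
    sums$bias <- bias
    sums
}

#' Restrict gene calls to informative heterozygous regions
#'
#' For PGA samples only genes whose transcript span lies entirely inside
#' a heterozygous genotype segment are informative; all others
#' (including genes straddling a segment boundary or on unassigned
#' chromosomes) are set to `NOT_INFORMATIVE`.
#'
#' @param calls output of [callGenes()].
#' @param genes a [GeneModels-class] object.
#' @param map a [GenotypeMap-class] object, or `NULL` (fully
#'   heterozygous sample: calls returned unchanged).
#' @return the calls table with non-heterozygous genes masked.
#' @export
restrictToHet <- function(calls, genes, map = NULL) {
    if (is.null(map)) return(calls)
    het <- heterozygousRegions(map)
    g <- geneTable(genes)
    g <- g[match(calls$gene_id, g$gene_id), , drop = FALSE]
    inside <- vapply(seq_len(nrow(g)), function(i) {
        h <- het[het$chrom == g$chrom[i], , drop = FALSE]
        any(g$start[i] >= h$start & g$end[i] <= h$end)
    }, logical(1))
    calls$status[!inside] <- "NOT_INFORMATIVE"
    calls$bias[!inside] <- "NO_CALL"
    calls
}

#' Cohort-level coverage filter for the global analysis
#'
#' A gene enters the global allele-specific analysis only when it has
#' allelic coverage in every sample, exceeding `cohortMinCellline`
#' total counts in every cell-line (ESC/EpiSC) sample and
#' `cohortMinEmbryo` in every embryonic sample.
#'
#' @param callsList named list of [callGenes()] tables, one per sample.
#' @param sampleClass character vector (same names/order) with values
#'   `"cellline"` or `"embryonic"`.
#' @param config an [expressionFilterConfig()] list.
#' @return character vector of surviving gene ids.
#' @export
cohortFilter <- function(callsList, sampleClass,
                         config = expressionFilterConfig()) {
    stopifnot(length(callsList) == length(sampleClass),
              all(sampleClass %in% c("cellline", "embryonic")))
    ids <- callsList[[1]]$gene_id
    keep <- rep(TRUE, length(ids))
    for (i in seq_along(callsList)) {
        tot <- callsList[[i]]$total[match(ids, callsList[[i]]$gene_id)]
        thr <- if (sampleClass[i] == "cellline")
            config$cohortMinCellline else config$cohortMinEmbryo
        keep <- keep & !is.na(tot) & tot > thr
    }
    ids[keep]
}

#' Aggregate allelic counts over arbitrary intervals
#'
#' Same contract as the gene-level summation but over ad hoc half-open
#' intervals (for instance ChIP enrichment peaks): counts over the SNP
#' sites inside each interval are summed and the maternal ratio
#' reported.
#'
#' @param x an [AllelicCounts-class] object.
#' @param intervals `data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `name`.
#' @return `data.frame` per interval with `mat_count`, `pat_count`,
#'   `total`, `ratio_mat` (`NA` when empty).
#' @export
aggregateIntervals <- function(x, intervals) {
    df <- countsTable(x)
    n <- nrow(intervals)
    out <- data.frame(chrom = intervals$chrom,
                      start = intervals$start, end = intervals$end,
                      name = if (!is.null(intervals$name))
                          intervals$name else sprintf("iv%03d", seq_len(n)),
                      mat_count = 0, pat_count = 0,
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        sel <- df$chrom == intervals$chrom[i] &
            df$pos >= intervals$start[i] & df$pos < intervals$end[i]
        out$mat_count[i] <- sum(df$mat_count[sel])
        out$pat_count[i] <- sum(df$pat_count[sel])
    }
    out$total <- out$mat_count + out$pat_count
    out$ratio_mat <- ifelse(out$total > 0, out$mat_count / out$total,
                            NA_real_)
    out
}

#' Write gene calls as TSV
#' @param calls output of [callGenes()].
#' @param path output file.
#' @export
writeGeneCalls <- function(calls, path) {
    write.table(calls, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
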