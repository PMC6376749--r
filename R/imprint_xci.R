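#' Normalized expression proxy from allelic counts
#'
#' Counts-per-kilobase-per-billion: `1e9 * gene total / (sample grand
#' total * exonic length in bp)`.  This proxies RPKM from the
#' SNP-overlapping read counts only; it is monotone in abundance at
#' fixed SNP density but not comparable in absolute value to
#' alignment-based RPKM.
#'
#' @param x an [AllelicCounts-class] object.
#' @param genes a [GeneModels-class] object.
#' @param sums optional precomputed [geneAllelicCounts()] table.
#' @return `data.frame` with `gene_id`, `total`, `expression`.
#' @export
sampleExpression <- function(x, genes, sums = NULL) {
    if (is.null(sums)) sums <- geneAllelicCounts(x, genes)
    df <- countsTable(x)
    grand <- sum(df$mat_count) + sum(df$pat_count)
    g <- geneTable(genes)
    len <- g$exonic_length[match(sums$gene_id, g$gene_id)]
    expr <- ifelse(grand > 0 & len > 0,
                   1e9 * sums$total / (grand * len), 0)
    data.frame(gene_id = sums$gene_id, total = sums$total,
               expression = expr, stringsAsFactors = FALSE)
}

#' Imprinting-status matrix across samples
#'
#' Classifies every catalogued imprinted gene in every sample by its
#' maternal ratio: a paternally expressed ("P") gene is a consistent
#' imprint when the ratio is below `1 - biasThreshold`, reversed when
#' above `biasThreshold`, and biallelic (loss of imprinting) in
#' between; symmetric for maternally expressed ("M") genes.  Genes
#' without a passing call in a sample are `no_data`.
#'
#' @param callsList named list of [callGenes()] tables, one per sample.
#' @param catalog `data.frame` with `gene_id` and `parent` in
#'   `c("P", "M")` (the compiled imprinted-gene list, or simulation
#'   truth).
#' @param config an [expressionFilterConfig()] list.
#' @return character matrix genes x samples with values
#'   `consistent`, `reversed`, `biallelic`, `no_data`; the maternal
#'   ratios are attached as attribute `"ratio"`.
#' @export
imprintTable <- function(callsList, catalog,
                         config = expressionFilterConfig()) {
    stopifnot(all(catalog$parent %in% c("P", "M")))
    genes <- catalog$gene_id
    out <- matrix("no_data", nrow = length(genes),
                  ncol = length(callsList),
                  dimnames = list(genes, names(callsList)))
    rat <- matrix(NA_real_, nrow = length(genes),
                  ncol = length(callsList),
                  dimnames = list(genes, names(callsList)))
    for (s in seq_along(callsList)) {
        calls <- callsList[[s]]
        m <- match(genes, calls$gene_id)
        absent <- is.na(m)
        if (any(absent))
            message(sum(absent), " catalog gene(s) absent from sample ",
                    names(callsList)[s])
        ok <- !absent & calls$status[m] == "PASS"
        r <- calls$ratio_mat[m]
        rat[ok, s] <- r[ok]
        out[ok, s] <- imprintStatus(r[ok], catalog$parent[ok], config)
    }
    attr(out, "ratio") <- rat
    out
}

#' Imprint status of a ratio given the catalogued parent of origin
#'
#' Pure classification function behind [imprintTable()].
#'
#' @param ratioMat maternal ratio in `[0, 1]`.
#' @param parent `"P"` (paternally expressed) or `"M"` (maternally
#'   expressed), recycled.
#' @param config an [expressionFilterConfig()] list.
#' @return character vector: `consistent`, `reversed` or `biallelic`.
#' @export
imprintStatus <- function(ratioMat, parent,
                          config = expressionFilterConfig()) {
    thr <- config$biasThreshold
    parent <- rep(parent, length.out = length(ratioMat))
    hi <- ratioMat > thr
    lo <- ratioMat < 1 - thr
    ifelse(parent == "P",
           ifelse(lo, "consistent", ifelse(hi, "reversed", "biallelic")),
           ifelse(hi, "consistent", ifelse(lo, "reversed", "biallelic")))
}

#' Expression fold changes between fertilized and PGA samples
#'
#' Per gene, `fold = (mean PGA expression + pseudocount) /
#' (mean fertilized expression + pseudocount)`; genes with zero
#' expression in both groups are skipped.  Class means are geometric.
#' In a parthenogenote both alleles carry the maternal epigenotype, so
#' paternally expressed genes are expected to drop (silenced) and
#' maternally expressed genes to double (the silent paternal allele is
#' replaced by an active maternal one).
#'
#' @param exprFert,exprPga lists of [sampleExpression()] tables for the
#'   fertilized and the PGA group.
#' @param catalog `data.frame` with `gene_id`, `parent` in `c("P","M")`.
#' @param pseudocount added to both group means (default 1 expression
#'   unit; guards fully silenced genes).
#' @return list with `genes` (per-gene table: `gene_id`, `parent`,
#'   `mean_fert`, `mean_pga`, `fold`) and `classes` (per-class geometric
#'   mean fold and gene count).
#' @export
pgaFoldChanges <- function(exprFert, exprPga, catalog, pseudocount = 1) {
    stopifnot(length(exprFert) >= 1, length(exprPga) >= 1)
    gmean <- function(tabs, ids) {
        m <- sapply(tabs, function(t)
            t$expression[match(ids, t$gene_id)])
        rowMeans(matrix(m, nrow = length(ids)))
    }
    ids <- catalog$gene_id
    mf <- gmean(exprFert, ids)
    mp <- gmean(exprPga, ids)
    keep <- !(is.na(mf) | is.na(mp)) & (mf > 0 | mp > 0)
    genes <- data.frame(gene_id = ids[keep],
                        parent = catalog$parent[keep],
                        mean_fert = mf[keep], mean_pga = mp[keep],
                        fold = (mp[keep] + pseudocount) /
                            (mf[keep] + pseudocount),
                        stringsAsFactors = FALSE)
    classes <- do.call(rbind, lapply(split(genes, genes$parent),
        function(d) data.frame(parent = d$parent[1],
                               n = nrow(d),
                               geo_mean_fold = exp(mean(log(d$fold))),
                               stringsAsFactors = FALSE)))
    rownames(classes) <- NULL
    list(genes = genes, classes = classes)
}

#' X-inactivation skew analysis
#'
#' Summarizes X-linked allelic ratios against Xist for one female
#' sample.  X-linked genes (excluding Xist) enter the summary when they
#' pass the gene-level filters and, if a balanced reference sample is
#' supplied, show less than `xciReferenceMaxFold` allelic bias there.
#' The skew call requires a passing Xist call: Xist fully biased to one
#' allele with the median X-linked ratio reciprocal gives
#' `FULLY_SKEWED_MAT_Xi` / `FULLY_SKEWED_PAT_Xi` (named for the
#' parental origin of the inactive X that Xist marks); both near 0.5
#' gives `BALANCED`; anything else `NO_CALL`.  The report also carries
#' median expression of X-linked versus autosomal genes for the dosage
#' comparison.
#'
#' @param calls [callGenes()] table of the sample.
#' @param expr [sampleExpression()] table of the sample.
#' @param xGenes character vector of X-linked gene ids (including
#'   `xistId`).
#' @param xistId the Xist-like gene id.
#' @param sex sample sex (`"XX"` required for a call).
#' @param refCalls optional [callGenes()] table of a balanced reference
#'   sample implementing the inclusion filter.
#' @param config an [expressionFilterConfig()] list.
#' @param balancedBand ratio band for `BALANCED` (default 0.35--0.65).
#' @return list of class `"XciReport"`: `skew_call`, `xist_ratio_mat`,
#'   `median_x_ratio`, `n_genes_included`, `x_gene_ratios`,
#'   `median_x_expression`, `median_autosome_expression`, `reason`.
#' @export
xciAnalysis <- function(calls, expr, xGenes, xistId, sex = "XX",
                        refCalls = NULL,
                        config = expressionFilterConfig(),
                        balancedBand = c(0.35, 0.65)) {
    rep0 <- function(call, reason) structure(
        list(skew_call = call, xist_ratio_mat = NA_real_,
             median_x_ratio = NA_real_, n_genes_included = 0L,
             x_gene_ratios = numeric(0),
             median_x_expression = NA_real_,
             median_autosome_expression = NA_real_, reason = reason),
        class = "XciReport")
    if (!identical(sex, "XX"))
        return(rep0("NO_CALL", "sample is not XX"))
    xi <- calls[calls$gene_id == xistId, , drop = FALSE]
    if (nrow(xi) != 1 || xi$status != "PASS")
        return(rep0("NO_CALL", "Xist without passing allelic call"))
    xist_ratio <- xi$ratio_mat

    xset <- setdiff(xGenes, xistId)
    sel <- calls$gene_id %in% xset & calls$status == "PASS"
    if (!is.null(refCalls)) {
        r <- refCalls$ratio_mat[match(calls$gene_id, refCalls$gene_id)]
        fold <- pmax(r, 1 - r) / pmin(r, 1 - r)
        sel <- sel & !is.na(fold) & fold < config$xciReferenceMaxFold
    }
    ratios <- calls$ratio_mat[sel]
    med <- if (length(ratios)) median(ratios) else NA_real_

    thr <- config$biasThreshold
    call <- "NO_CALL"
    if (!is.na(med)) {
        if (xist_ratio > thr && med < 1 - thr)
            call <- "FULLY_SKEWED_MAT_Xi"
        else if (xist_ratio < 1 - thr && med > thr)
            call <- "FULLY_SKEWED_PAT_Xi"
        else if (xist_ratio >= balancedBand[1] &&
                 xist_ratio <= balancedBand[2] &&
                 med >= balancedBand[1] && med <= balancedBand[2])
            call <- "BALANCED"
    }
    ex <- expr$expression[match(calls$gene_id, expr$gene_id)]
    on_x <- calls$gene_id %in% xGenes
    structure(list(
        skew_call = call, xist_ratio_mat = xist_ratio,
        median_x_ratio = med,
        n_genes_included = length(ratios),
        x_gene_ratios = setNames(ratios, calls$gene_id[sel]),
        median_x_expression = median(ex[on_x & calls$total > 0],
                                     na.rm = TRUE),
        median_autosome_expression = median(ex[!on_x & calls$total > 0],
                                            na.rm = TRUE),
        reason = NA_character_), class = "XciReport")
}

#' @exportS3Method base::print
print.XciReport <- function(x, ...) {
    cat("XciReport:", x$skew_call, "\n")
    if (!is.na(x$xist_ratio_mat))
        cat(sprintf("  Xist maternal ratio %.3f; median X-gene ratio %.3f over %d genes\n",
                    x$xist_ratio_mat, x$median_x_ratio,
                    x$n_genes_included))
    if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
    invisible(x)
}
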