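#' @import methods
#' @importFrom stats rpois rbinom rbeta rlnorm runif median sd setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

.BIN_LABELS <- c("PAT_HOM", "HET", "MAT_HOM", "INSUFFICIENT")
.SEG_LABELS <- c("PAT_HOM", "HET", "MAT_HOM", "UNASSIGNED")
.IMPRINT_CLASSES <- c("MAT_EXPR", "PAT_EXPR", "BIASED", "BIALLELIC", "XIST")

.check_counts_df <- function(df) {
    need <- c("chrom", "pos", "mat_count", "pat_count")
    if (!all(need %in% names(df)))
        return(sprintf("counts table must have columns %s",
                       paste(need, collapse = ", ")))
    if (any(df$mat_count < 0) || any(df$pat_count < 0))
        return("allelic counts must be non-negative")
    if (any(df$pos < 0))
        return("positions must be >= 0 (0-based coordinates)")
    key <- paste(df$chrom, df$pos)
    if (anyDuplicated(key))
        return("duplicate (chrom, pos) records are not allowed")
    ord <- order(df$chrom, df$pos)
    if (!identical(ord, seq_len(nrow(df))))
        return("records must be sorted by (chrom, pos)")
    TRUE
}

#' Per-sample allelic count table
#'
#' Holds, for one sample, read counts assigned to the maternal and paternal
#' allele at each discriminating SNP site, together with the chromosome
#' lengths that define the binning universe.  Coordinates are 0-based.
#'
#' @slot sampleId single character sample label.
#' @slot counts `data.frame` with columns `chrom`, `pos`, `mat_count`,
#'   `pat_count`, sorted by `(chrom, pos)`, one row per site.
#' @slot chromLengths named numeric vector of chromosome lengths in bp.
#'
#' @exportClass AllelicCounts
setClass("AllelicCounts",
    slots = c(sampleId = "character",
              counts = "data.frame",
              chromLengths = "numeric"))

setValidity("AllelicCounts", function(object) {
    if (length(object@sampleId) != 1L)
        return("sampleId must be a single string")
    msg <- .check_counts_df(object@counts)
    if (!isTRUE(msg)) return(msg)
    if (is.null(names(object@chromLengths)) &&
        length(object@chromLengths) > 0)
        return("chromLengths must be named")
    df <- object@counts
    if (nrow(df) > 0) {
        unknown <- setdiff(unique(df$chrom), names(object@chromLengths))
        if (length(unknown))
            return(sprintf("chromosome(s) without declared length: %s",
                           paste(unknown, collapse = ", ")))
        len <- object@chromLengths[df$chrom]
        if (any(df$pos >= len))
            return("site position beyond declared chromosome length")
    }
    TRUE
})

#' Gene models with exon intervals and exonic SNP sites
#'
#' Exon coordinates are 0-based half-open.  Each gene carries the SNP sites
#' of the supplied map that fall strictly inside its exon blocks; genes
#' without exonic SNPs are retained but flagged uninformative.
#'
#' @slot genes `data.frame` with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (transcript span), `exonic_length`,
#'   `n_sites`, `informative`.
#' @slot exons `data.frame` with columns `gene_id`, `chrom`, `start`, `end`.
#' @slot sites `data.frame` mapping exonic SNPs to genes: `gene_id`,
#'   `chrom`, `pos`.
#'
#' @exportClass GeneModels
setClass("GeneModels",
    slots = c(genes = "data.frame",
              exons = "data.frame",
              sites = "data.frame"))

setValidity("GeneModels", function(object) {
    g <- object@genes
    need <- c("gene_id", "chrom", "strand", "start", "end",
              "exonic_length", "n_sites", "informative")
    if (!all(need %in% names(g)))
        return(sprintf("genes table must have columns %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(g$gene_id))
        return("duplicate gene_id")
    e <- object@exons
    if (nrow(e) > 0 && any(e$end <= e$start))
        return("exon intervals must be non-empty [start, end)")
    # exonic_length must equal the sum of exon widths, exons non-overlapping
    if (nrow(e) > 0) {
        w <- tapply(e$end - e$start, e$gene_id, sum)
        m <- match(g$gene_id, names(w))
        bad <- which(!is.na(m) & g$exonic_length != as.numeric(w[m]))
        if (length(bad))
            return("exonic_length inconsistent with exon intervals")
    }
    TRUE
})

#' Reconstructed genotype map of one sample
#'
#' Per-chromosome tiling into maternal-homozygous, heterozygous,
#' paternal-homozygous (or unassigned) segments, with the crossover
#' breakpoints separating them, the underlying classified bins, and a
#' chromosome-level allelic-imbalance flag (e.g. trisomy signature).
#'
#' @slot sampleId sample label.
#' @slot binSizeMb bin size (MB) used for the calls.
#' @slot bins `data.frame`: `chrom`, `bin`, `start`, `end`, `mat_count`,
#'   `pat_count`, `total`, `pct_mat`, `pct_smoothed`, `label`.
#' @slot segments `data.frame`: `chrom`, `start`, `end`, `label`,
#'   `mean_pct` (bp coordinates, half-open).
#' @slot breakpoints `data.frame`: `chrom`, `pos`, `left_label`,
#'   `right_label` (`pos` = start of the first bin of the new segment).
#' @slot imbalance `data.frame`: `chrom`, `het_pct_mat`, `flagged`.
#'
#' @exportClass GenotypeMap
setClass("GenotypeMap",
    slots = c(sampleId = "character",
              binSizeMb = "numeric",
              bins = "data.frame",
              segments = "data.frame",
              breakpoints = "data.frame",
              imbalance = "data.frame"))

setValidity("GenotypeMap", function(object) {
    s <- object@segments
    if (nrow(s) > 0) {
        if (!all(s$label %in% .SEG_LABELS))
            return("unknown segment label")
        for (ch in unique(s$chrom)) {
            ss <- s[s$chrom == ch, , drop = FALSE]
            if (any(diff(ss$start) <= 0))
                return("segments must be ordered within chromosome")
            if (nrow(ss) > 1 &&
                any(ss$start[-1] != ss$end[-nrow(ss)]))
                return("segments must tile the chromosome")
            if (any(ss$label[-1] == ss$label[-nrow(ss)]))
                return("adjacent segment labels must differ")
        }
    }
    TRUE
})

#' Ground truth of a synthetic sample set
#'
#' Generator-side truth used to score recovery: genotype segments and
#' crossover positions per chromosome, plus per-gene imprint classes and
#' baseline abundances.
#'
#' @slot segments `data.frame`: `chrom`, `start`, `end`, `state` in
#'   `HOM_MAT`, `HOM_PAT`, `HET` (bp, half-open, tiling each chromosome).
#' @slot crossovers `data.frame`: `chrom`, `pos` (bp).
#' @slot genes `data.frame`: `gene_id`, `chrom`, `start`, `end`, `class`,
#'   `bias`, `abundance`, `is_x`, `is_xist`.
#' @slot chromLengths named numeric vector (bp).
#'
#' @exportClass SimTruth
setClass("SimTruth",
    slots = c(segments = "data.frame",
              crossovers = "data.frame",
              genes = "data.frame",
              chromLengths = "numeric"))

setValidity("SimTruth", function(object) {
    s <- object@segments
    if (nrow(s) > 0) {
        if (!all(s$state %in% c("HOM_MAT", "HOM_PAT", "HET")))
            return("unknown genotype state")
        for (ch in unique(s$chrom)) {
            ss <- s[s$chrom == ch, , drop = FALSE]
            if (ss$start[1] != 0)
                return("segments must start at 0")
            if (nrow(ss) > 1 && any(ss$start[-1] != ss$end[-nrow(ss)]))
                return("segments must tile the chromosome")
            if (!is.na(object@chromLengths[ch]) &&
                ss$end[nrow(ss)] != object@chromLengths[[ch]])
                return("segments must end at the chromosome length")
        }
    }
    g <- object@genes
    if (nrow(g) > 0 && !all(g$class %in% .IMPRINT_CLASSES))
        return("unknown imprint class")
    TRUE
})

setMethod("show", "AllelicCounts", function(object) {
    df <- object@counts
    cat(sprintf("AllelicCounts '%s': %d sites on %d chromosome(s)\n",
                object@sampleId, nrow(df),
                length(unique(df$chrom))))
    cat(sprintf("  grand total: %d maternal + %d paternal = %d reads\n",
                sum(df$mat_count), sum(df$pat_count),
                sum(df$mat_count) + sum(df$pat_count)))
})

setMethod("show", "GeneModels", function(object) {
    cat(sprintf("GeneModels: %d genes (%d informative), %d exons, %d exonic SNP sites\n",
                nrow(object@genes), sum(object@genes$informative),
                nrow(object@exons), nrow(object@sites)))
})

setMethod("show", "GenotypeMap", function(object) {
    cat(sprintf("GenotypeMap '%s' at %g MB resolution\n",
                object@sampleId, object@binSizeMb))
    cat(sprintf("  %d segment(s), %d breakpoint(s) on %d chromosome(s)\n",
                nrow(object@segments), nrow(object@breakpoints),
                length(unique(object@segments$chrom))))
    tab <- table(factor(object@segments$label, levels = .SEG_LABELS))
    cat("  segment labels:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d chromosome(s), %d crossover(s), %d gene(s)\n",
                length(object@chromLengths), nrow(object@crossovers),
                nrow(object@genes)))
})
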