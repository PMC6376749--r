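#' Construct an AllelicCounts object
#'
#' @param sampleId sample label.
#' @param counts `data.frame` with columns `chrom`, `pos` (0-based),
#'   `mat_count`, `pat_count`.  Unsorted input is sorted with a warning;
#'   duplicate sites and negative counts are errors.
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#'   If omitted, lengths are taken as `max(pos) + 1` per chromosome.
#' @return an [AllelicCounts-class] object.
#' @export
AllelicCounts <- function(sampleId, counts, chromLengths = NULL) {
    counts <- as.data.frame(counts)
    counts$chrom <- as.character(counts$chrom)
    counts$pos <- as.numeric(counts$pos)
    counts$mat_count <- as.numeric(counts$mat_count)
    counts$pat_count <- as.numeric(counts$pat_count)
    ord <- order(counts$chrom, counts$pos)
    if (!identical(ord, seq_len(nrow(counts)))) {
        warning("counts were not sorted by (chrom, pos); sorting")
        counts <- counts[ord, , drop = FALSE]
        rownames(counts) <- NULL
    }
    if (is.null(chromLengths)) {
        if (nrow(counts) > 0) {
            chromLengths <- tapply(counts$pos, counts$chrom, max) + 1
            chromLengths <- setNames(as.numeric(chromLengths),
                                     names(chromLengths))
        } else chromLengths <- numeric(0)
    }
    new("AllelicCounts", sampleId = as.character(sampleId),
        counts = counts, chromLengths = chromLengths)
}

#' Read a maternal/paternal SNP map
#'
#' Reads the catalogue of sites discriminating the maternal from the
#' paternal genome, either as a 4-column TSV (`chrom`, `pos`,
#' `maternal_base`, `paternal_base`; positions 0-based) or as a minimal
#' VCF where by convention REF is the maternal and ALT the paternal
#' allele (`maternalRef = FALSE` flips this).  VCF positions (1-based)
#' are converted to the package-wide 0-based convention.  Indel and
#' multi-allelic records are skipped with a message; duplicate positions
#' are an error.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`; default guessed from the extension.
#' @param maternalRef logical; when reading VCF, does REF carry the
#'   maternal allele?
#' @return `data.frame` with columns `chrom`, `pos`, `maternal_base`,
#'   `paternal_base`, sorted by `(chrom, pos)`.
#' @export
readSnpMap <- function(path, format = c("auto", "tsv", "vcf"),
                       maternalRef = TRUE) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (format == "vcf") {
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
        ref <- fx$REF
        alt <- fx$ALT
        snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
            ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
        if (any(!snv))
            message(sum(!snv),
                    " non-SNV (indel/multi-allelic) record(s) skipped")
        df <- data.frame(chrom = fx$CHROM[snv],
                         pos = as.numeric(fx$POS[snv]) - 1,
                         maternal_base = ref[snv],
                         paternal_base = alt[snv],
                         stringsAsFactors = FALSE)
        if (!maternalRef)
            df[, c("maternal_base", "paternal_base")] <-
                df[, c("paternal_base", "maternal_base")]
    } else {
        df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
        if (ncol(df) < 4)
            stop("SNP map TSV needs 4 columns: chrom pos maternal paternal")
        names(df)[1:4] <- c("chrom", "pos", "maternal_base", "paternal_base")
        df <- df[, 1:4]
        df$chrom <- as.character(df$chrom)
        df$pos <- as.numeric(df$pos)
        bad <- which(is.na(df$pos))
        if (length(bad))
            stop("malformed SNP record at data line ", bad[1])
    }
    if (nrow(df) == 0) {
        warning("SNP map is empty")
        return(df)
    }
    if (any(df$maternal_base == df$paternal_base))
        stop("maternal and paternal alleles identical at some site(s)")
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    if (anyDuplicated(paste(df$chrom, df$pos)))
        stop("duplicate (chrom, pos) in SNP map")
    rownames(df) <- NULL
    df
}

#' Write a SNP map as TSV
#' @param snps SNP map `data.frame` as returned by [readSnpMap()].
#' @param path output file.
#' @export
writeSnpMap <- function(snps, path) {
    write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write per-sample allelic counts
#'
#' TSV with header `chrom pos mat_count pat_count`, positions 0-based.
#'
#' @param path file path.
#' @param sampleId sample label (default: file name without extension).
#' @param chromLengths optional named vector of chromosome lengths.
#' @return [readCounts()] returns an [AllelicCounts-class] object.
#' @export
readCounts <- function(path, sampleId = NULL, chromLengths = NULL) {
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(path))
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "mat_count", "pat_count")
    if (!all(need %in% names(df)))
        stop("counts TSV must have header columns: ",
             paste(need, collapse = " "))
    if (any(df$mat_count < 0 | df$pat_count < 0))
        stop("negative allelic count in ", path)
    AllelicCounts(sampleId, df[, need], chromLengths)
}

#' @rdname readCounts
#' @param x an [AllelicCounts-class] object.
#' @export
writeCounts <- function(x, path) {
    stopifnot(is(x, "AllelicCounts"))
    write.table(countsTable(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read gene models from BED12 and attach exonic SNP sites
#'
#' Exon blocks are taken from the BED12 block fields; coordinates are kept
#' in the native 0-based half-open convention.  Each gene receives exactly
#' the SNPs of `snps` lying inside its exon blocks (a SNP at an exon end
#' coordinate is outside, by half-openness).  Genes without exonic SNPs
#' are retained and flagged uninformative.
#'
#' @param path BED12 file.
#' @param snps SNP map `data.frame` (see [readSnpMap()]); may be `NULL`
#'   for pure interval use.
#' @return a [GeneModels-class] object.
#' @export
readGeneModels <- function(path, snps = NULL) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$blocks))
        stop("BED input lacks block (exon) fields; BED12 required")
    nblocks <- lengths(gr$blocks)
    ids <- as.character(gr$name)
    if (any(is.na(ids)) || anyDuplicated(ids))
        stop("BED12 names must be unique gene identifiers")
    # blocks from rtracklayer are 1-based, relative to the gene start
    gstart0 <- GenomicRanges::start(gr) - 1L
    exdf <- do.call(rbind, lapply(seq_along(gr), function(i) {
        b <- gr$blocks[[i]]
        data.frame(gene_id = ids[i],
                   chrom = as.character(GenomicRanges::seqnames(gr)[i]),
                   start = gstart0[i] + IRanges::start(b) - 1L,
                   end = gstart0[i] + IRanges::end(b),
                   stringsAsFactors = FALSE)
    }))
    genes <- data.frame(gene_id = ids,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        strand = as.character(GenomicRanges::strand(gr)),
                        start = gstart0,
                        end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
    .buildGeneModels(genes, exdf, snps)
}

# Assemble a GeneModels object from plain tables, assigning exonic SNPs.
.buildGeneModels <- function(genes, exons, snps) {
    ord <- order(exons$gene_id, exons$start)
    exons <- exons[ord, , drop = FALSE]
    genes$exonic_length <- 0
    w <- tapply(exons$end - exons$start, exons$gene_id, sum)
    m <- match(genes$gene_id, names(w))
    genes$exonic_length[!is.na(m)] <- as.numeric(w[m[!is.na(m)]])
    sites <- data.frame(gene_id = character(0), chrom = character(0),
                        pos = numeric(0), stringsAsFactors = FALSE)
    if (!is.null(snps) && nrow(snps) > 0 && nrow(exons) > 0) {
        exgr <- GenomicRanges::GRanges(
            exons$chrom,
            IRanges::IRanges(exons$start + 1L, exons$end))
        sgr <- GenomicRanges::GRanges(
            snps$chrom, IRanges::IRanges(snps$pos + 1L, snps$pos + 1L))
        ov <- GenomicRanges::findOverlaps(sgr, exgr)
        if (length(ov)) {
            sites <- data.frame(
                gene_id = exons$gene_id[S4Vectors::subjectHits(ov)],
                chrom = snps$chrom[S4Vectors::queryHits(ov)],
                pos = snps$pos[S4Vectors::queryHits(ov)],
                stringsAsFactors = FALSE)
            sites <- unique(sites)
            sites <- sites[order(sites$gene_id, sites$pos), , drop = FALSE]
            rownames(sites) <- NULL
        }
    }
    ns <- table(sites$gene_id)
    genes$n_sites <- as.integer(ns[genes$gene_id])
    genes$n_sites[is.na(genes$n_sites)] <- 0L
    genes$informative <- genes$n_sites > 0L
    rownames(genes) <- NULL
    new("GeneModels", genes = genes, exons = exons, sites = sites)
}

#' Write gene models as BED12
#' @param genes a [GeneModels-class] object.
#' @param path output file.
#' @export
writeGeneModels <- function(genes, path) {
    g <- geneTable(genes)
    e <- exonTable(genes)
    lines <- vapply(seq_len(nrow(g)), function(i) {
        ei <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
        ei <- ei[order(ei$start), , drop = FALSE]
        paste(g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0,
              g$strand[i], g$start[i], g$end[i], 0, nrow(ei),
              paste0(paste(ei$end - ei$start, collapse = ","), ","),
              paste0(paste(ei$start - g$start[i], collapse = ","), ","),
              sep = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write genotype segments as BED5-like text
#'
#' Columns: `chrom start end label mean_pct` (0-based half-open).
#'
#' @param map a [GenotypeMap-class] object.
#' @param path output file.
#' @export
writeSegments <- function(map, path) {
    s <- genotypeSegments(map)
    write.table(s[, c("chrom", "start", "end", "label", "mean_pct")],
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
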