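# In-code fixtures shared across test files.

write_tmp <- function(lines, ext = ".txt") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

tiny_snp_tsv <- function() {
    write_tmp(c("chrom\tpos\tmaternal_base\tpaternal_base",
                "chr1\t100\tA\tG",
                "chr1\t600\tC\tT",
                "chr2\t50\tG\tA"), ".tsv")
}

tiny_vcf <- function() {
    write_tmp(c("##fileformat=VCFv4.2",
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                "chr1\t101\t.\tA\tG\t.\t.\t.",
                "chr1\t201\t.\tC\tT\t.\t.\t.",
                "chr1\t301\t.\tG\tA,T\t.\t.\t.",
                "chr2\t51\t.\tT\tC\t.\t.\t.",
                "chr2\t151\t.\tA\tC\t.\t.\t."), ".vcf")
}

# one gene, exons [0,100) and [200,300)
tiny_bed12 <- function() {
    write_tmp(paste("chr1", 0, 300, "geneA", 0, "+", 0, 300, 0, 2,
                    "100,100,", "0,200,", sep = "\t"), ".bed")
}

counts_df <- function(chrom, pos, mat, pat) {
    data.frame(chrom = chrom, pos = pos, mat_count = mat,
               pat_count = pat, stringsAsFactors = FALSE)
}

# AllelicCounts whose 1 MB bins carry the given expected labels, built
# from one site per bin with unambiguous counts
counts_from_labels <- function(labels, binSizeMb = 1,
                               perBin = 30) {
    n <- length(labels)
    pos <- (seq_len(n) - 1) * binSizeMb * 1e6 + 1000
    mat <- integer(n); pat <- integer(n)
    mat[labels == "MAT_HOM"] <- perBin
    pat[labels == "PAT_HOM"] <- perBin
    het <- labels == "HET"
    mat[het] <- perBin / 2
    pat[het] <- perBin / 2
    keep <- labels != "INSUFFICIENT"
    AllelicCounts("labelled",
                  counts_df(rep("chr1", sum(keep)), pos[keep],
                            mat[keep], pat[keep]),
                  c(chr1 = n * binSizeMb * 1e6))
}

# BED12 line with non-scientific number formatting
bed_line <- function(chrom, start, end, name, strand, sizes, starts) {
    fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
    paste(chrom, fmt(start), fmt(end), name, 0, strand, fmt(start),
          fmt(end), 0, length(sizes),
          paste0(paste(fmt(sizes), collapse = ","), ","),
          paste0(paste(fmt(starts), collapse = ","), ","), sep = "\t")
}
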