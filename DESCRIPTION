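Package: asePGA
Title: Allele-Specific RNA-Seq Genotyping and Imprinting Analysis for
    F1-Hybrid and Parthenogenetic Mouse Lines
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for allele-specific RNA-seq analysis of F1-hybrid mouse
    samples (maternal C57BL/6J x paternal DBA/2J and similar crosses).
    Implements RNA-seq-based genotype reconstruction of parthenogenetic
    (PGA) cell lines from binned allelic read counts, including meiotic
    crossover-breakpoint calling and restriction of downstream analysis to
    informative heterozygous regions; gene-level allele-specific
    quantification with coverage and consistency filters and allelic-bias
    classification; study-level summaries of genomic imprinting, expression
    fold changes between fertilized and PGA-derived lines, and X-chromosome
    inactivation skewing from Xist and X-linked allelic ratios.  A seeded
    synthetic-data generator emulates SNP maps, mosaic PGA genotypes,
    imprinted gene classes and overdispersed allelic read sampling so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
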