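#' Default scaled-down genome for simulations
#'
#' Five 100 MB autosomes plus a 100 MB X chromosome.  Full mouse-scale
#' chromosome lengths can be passed anywhere a `chromLengths` argument
#' is accepted.
#'
#' @param nAutosomes number of autosomes.
#' @param lengthMb chromosome length in MB.
#' @param withX include an X chromosome.
#' @return named numeric vector of lengths (bp).
#' @export
defaultChromLengths <- function(nAutosomes = 5, lengthMb = 100,
                                withX = TRUE) {
    len <- rep(lengthMb * 1e6, nAutosomes)
    names(len) <- paste0("chr", seq_len(nAutosomes))
    if (withX) len <- c(len, chrX = lengthMb * 1e6)
    len
}

# beta-binomial draws with correlation rho; rho = 0 degenerates to
# binomial, f of exactly 0 or 1 is deterministic (no reads can come from
# an absent or fully silent haplotype).
.rbetabinom <- function(n, size, f, rho) {
    out <- numeric(length(size))
    det <- f <= 0 | f >= 1 | rho <= 0
    if (any(det))
        out[det] <- rbinom(sum(det), size[det],
                           rep(f, length.out = length(size))[det])
    if (any(!det)) {
        fi <- rep(f, length.out = length(size))[!det]
        a <- fi * (1 - rho) / rho
        b <- (1 - fi) * (1 - rho) / rho
        p <- rbeta(sum(!det), a, b)
        out[!det] <- rbinom(sum(!det), size[!det], p)
    }
    out
}

#' Simulate a SNP map
#'
#' Site counts per chromosome are Poisson with mean `length * density`;
#' positions are uniform, deduplicated and sorted.  The default density
#' matches the roughly 1 discriminating SNP per 520 bp of a B6xDBA2 F1
#' genome; tests and simulations typically scale it down.
#'
#' @param chromLengths named numeric vector (bp).
#' @param density sites per bp (default `1/520`).
#' @param seed integer seed.
#' @return SNP map `data.frame` (`chrom`, `pos`, `maternal_base`,
#'   `paternal_base`), 0-based positions.
#' @export
makeSnpMap <- function(chromLengths, density = 1 / 520, seed = 1L) {
    stopifnot(density > 0, length(chromLengths) > 0)
    set.seed(seed)
    if (all(chromLengths * density < 1))
        warning("expected fewer than one site per chromosome; ",
                "genotyping will be undetermined")
    bases <- c("A", "C", "G", "T")
    out <- lapply(names(chromLengths), function(ch) {
        n <- rpois(1, chromLengths[[ch]] * density)
        if (n == 0)
            return(data.frame(chrom = character(0), pos = numeric(0),
                              maternal_base = character(0),
                              paternal_base = character(0)))
        pos <- sort(unique(floor(runif(n, 0, chromLengths[[ch]]))))
        mat <- sample(bases, length(pos), replace = TRUE)
        shift <- sample(1:3, length(pos), replace = TRUE)
        pat <- bases[(match(mat, bases) - 1L + shift) %% 4L + 1L]
        data.frame(chrom = ch, pos = pos, maternal_base = mat,
                   paternal_base = pat, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Simulate a mosaic PGA genotype
#'
#' Diploid parthenogenotes retain pericentromeric homozygosity: each
#' chromosome starts homozygous at the proximal end (the haplotype of
#' every homozygous run drawn maternal or paternal), and the state
#' alternates homozygous/heterozygous at each meiotic crossover.  Zero
#' crossovers give a fully homozygous chromosome.  Crossover positions
#' are uniform, strictly inside the chromosome, with pairwise gaps of at
#' least `minGapMb`.
#'
#' @param chromLengths named numeric vector (bp).
#' @param model a [crossoverModel()] list.
#' @param seed integer seed.
#' @return a [SimTruth-class] object (genotype part; no genes).
#' @export
simulatePgaGenotype <- function(chromLengths, model = crossoverModel(),
                                seed = 1L) {
    set.seed(seed)
    segl <- list(); xol <- list()
    for (ch in names(chromLengths)) {
        len <- chromLengths[[ch]]
        nmax <- min(model$nCrossoversRange[2],
                    floor(len / (model$minGapMb * 1e6)))
        nr <- model$nCrossoversRange[1]:max(model$nCrossoversRange[1], nmax)
        n <- nr[sample.int(length(nr), 1)]
        pos <- numeric(0)
        if (n > 0) {
            repeat {
                pos <- sort(floor(runif(n, 1, len)))
                if (n == 1 || all(diff(pos) >= model$minGapMb * 1e6)) break
            }
        }
        bounds <- c(0, pos, len)
        states <- rep(c("HOM", "HET"), length.out = n + 1)
        hap <- sample(c("HOM_MAT", "HOM_PAT"), sum(states == "HOM"),
                      replace = TRUE)
        states[states == "HOM"] <- hap
        segl[[ch]] <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                                 end = bounds[-1], state = states,
                                 stringsAsFactors = FALSE)
        xol[[ch]] <- if (n > 0) data.frame(chrom = ch, pos = pos)
                     else data.frame(chrom = character(0), pos = numeric(0))
    }
    new("SimTruth",
        segments = do.call(rbind, c(segl, list(make.row.names = FALSE))),
        crossovers = do.call(rbind, c(xol, list(make.row.names = FALSE))),
        genes = data.frame(), chromLengths = chromLengths)
}

#' Fully heterozygous F1 genotype (fertilized or nuclear-transfer lines)
#'
#' @param chromLengths named numeric vector (bp).
#' @return a [SimTruth-class] object with a single heterozygous segment
#'   per chromosome and no crossovers.
#' @export
f1Genotype <- function(chromLengths) {
    segs <- data.frame(chrom = names(chromLengths), start = 0,
                       end = as.numeric(chromLengths), state = "HET",
                       stringsAsFactors = FALSE)
    new("SimTruth", segments = segs,
        crossovers = data.frame(chrom = character(0), pos = numeric(0)),
        genes = data.frame(), chromLengths = chromLengths)
}

#' Simulate gene models with imprint classes
#'
#' Places non-overlapping multi-exon genes on the genome, assigns each
#' an imprint class (maternally expressed, paternally expressed, biased
#' toward the maternal allele, or biallelic) and a log-normal baseline
#' abundance.  Genes on `xChrom` are flagged X-linked and one of them is
#' designated Xist-like (expressed only from the inactive X).
#'
#' @param snps SNP map `data.frame`.
#' @param chromLengths named numeric vector (bp).
#' @param nGenes number of genes.
#' @param classProps named proportions over
#'   `c("MAT_EXPR","PAT_EXPR","BIASED","BIALLELIC")`.
#' @param biasLevel expected maternal fraction of `BIASED` genes
#'   (default 0.85, the strong-but-incomplete parental bias class).
#' @param nExonsRange,exonLenRange,intronLenRange gene geometry (bp).
#' @param xChrom name of the X chromosome in `chromLengths`, or `NULL`.
#' @param seed integer seed.
#' @return list with `genes` (a [GeneModels-class] object) and `truth`
#'   (a [SimTruth-class] object carrying the gene table).
#' @export
makeGeneModels <- function(snps, chromLengths, nGenes = 300,
                           classProps = c(MAT_EXPR = 0.10,
                                          PAT_EXPR = 0.10,
                                          BIASED = 0.05,
                                          BIALLELIC = 0.75),
                           biasLevel = 0.85,
                           nExonsRange = c(2, 5),
                           exonLenRange = c(200, 600),
                           intronLenRange = c(500, 5000),
                           xChrom = "chrX", seed = 1L) {
    stopifnot(nGenes >= 1, abs(sum(classProps) - 1) < 1e-8)
    set.seed(seed)
    occupied <- lapply(names(chromLengths), function(ch)
        IRanges::IRanges())
    names(occupied) <- names(chromLengths)
    generows <- list(); exonrows <- list()
    probs <- chromLengths / sum(chromLengths)
    for (i in seq_len(nGenes)) {
        placed <- FALSE
        for (try in seq_len(200)) {
            ch <- sample(names(chromLengths), 1, prob = probs)
            ne <- sample(nExonsRange[1]:nExonsRange[2], 1)
            ew <- floor(runif(ne, exonLenRange[1], exonLenRange[2]))
            iw <- if (ne > 1)
                floor(runif(ne - 1, intronLenRange[1], intronLenRange[2]))
                else numeric(0)
            span <- sum(ew) + sum(iw)
            if (span >= chromLengths[[ch]]) next
            st <- floor(runif(1, 0, chromLengths[[ch]] - span))
            ir <- IRanges::IRanges(st + 1, st + span)
            if (length(IRanges::findOverlaps(ir, occupied[[ch]])) > 0) next
            occupied[[ch]] <- c(occupied[[ch]], ir)
            exst <- st + cumsum(c(0, head(ew, -1) + iw))
            gid <- sprintf("gene%04d", i)
            exonrows[[i]] <- data.frame(gene_id = gid, chrom = ch,
                                        start = exst, end = exst + ew,
                                        stringsAsFactors = FALSE)
            generows[[i]] <- data.frame(gene_id = gid, chrom = ch,
                                        strand = sample(c("+", "-"), 1),
                                        start = st, end = st + span,
                                        stringsAsFactors = FALSE)
            placed <- TRUE
            break
        }
        if (!placed)
            stop("insufficient genome space to place ", nGenes, " genes")
    }
    genes <- do.call(rbind, c(generows, list(make.row.names = FALSE)))
    exons <- do.call(rbind, c(exonrows, list(make.row.names = FALSE)))
    gm <- .buildGeneModels(genes, exons, snps)

    cls <- sample(names(classProps), nGenes, replace = TRUE,
                  prob = classProps)
    g <- geneTable(gm)
    is_x <- if (is.null(xChrom)) rep(FALSE, nGenes) else g$chrom == xChrom
    is_xist <- rep(FALSE, nGenes)
    # X-linked genes are governed by X inactivation, not imprinting
    cls[is_x] <- "BIALLELIC"
    if (any(is_x)) {
        xi <- which(is_x)[1]
        is_xist[xi] <- TRUE
        cls[xi] <- "XIST"
    }
    truth_genes <- data.frame(
        gene_id = g$gene_id, chrom = g$chrom, start = g$start,
        end = g$end, class = cls,
        bias = ifelse(cls == "BIASED", biasLevel,
                      ifelse(cls == "MAT_EXPR", 1,
                             ifelse(cls == "PAT_EXPR", 0, 0.5))),
        abundance = rlnorm(nGenes, meanlog = log(10), sdlog = 1),
        is_x = is_x, is_xist = is_xist, stringsAsFactors = FALSE)
    # Xist is among the most abundant transcripts of cells with an
    # inactive X; pin it well above the coverage gates
    truth_genes$abundance[is_xist] <- 100
    truth <- new("SimTruth", segments = data.frame(),
                 crossovers = data.frame(chrom = character(0),
                                         pos = numeric(0)),
                 genes = truth_genes, chromLengths = chromLengths)
    list(genes = gm, truth = truth)
}

#' Expected maternal fraction and abundance scale per gene in a state
#'
#' Deterministic part of the generative model: given the genotype truth
#' and a cell state, returns for every gene the expected maternal read
#' fraction and the multiplicative abundance scale relative to the
#' fertilized baseline.  In PGA lines both alleles carry the maternal
#' epigenotype, so the abundance scales by twice the maternal share of
#' the class (silencing paternally expressed genes, doubling maternally
#' expressed ones) while the allelic fraction is dictated purely by the
#' haplotype segment the gene lies in (0.5 in heterozygous, 1 or 0 in
#' homozygous runs).
#'
#' @param truth a [SimTruth-class] object carrying genes and, for PGA,
#'   genotype segments.
#' @param state a [cellStateConfig()] list.
#' @param lossMask optional logical vector (per gene): imprint lost
#'   (collapses the class fraction to 0.5).  Drawn internally by
#'   [simulateSample()].
#' @return `data.frame` with `gene_id`, `f_expected`, `scale`.
#' @export
expectedMatFraction <- function(truth, state, lossMask = NULL) {
    g <- truthGenes(truth)
    stopifnot(nrow(g) > 0)
    leak <- state$paternalLeak
    f0 <- ifelse(g$class == "MAT_EXPR", 1 - leak,
          ifelse(g$class == "PAT_EXPR", leak,
          ifelse(g$class == "BIASED", g$bias, 0.5)))
    if (!is.null(lossMask))
        f0[lossMask & g$class %in% c("MAT_EXPR", "PAT_EXPR", "BIASED")] <- 0.5
    f <- f0
    scale <- rep(1, nrow(g))

    if (state$origin == "PGA") {
        scale <- 2 * f0
        segs <- truthSegments(truth)
        stopifnot(nrow(segs) > 0)
        # a gene straddling a crossover takes the state at its midpoint
        f <- vapply(seq_len(nrow(g)), function(i) {
            ss <- segs[segs$chrom == g$chrom[i], , drop = FALSE]
            mid <- (g$start[i] + g$end[i]) / 2
            k <- findInterval(mid, ss$start)
            if (k < 1 || mid >= ss$end[k])
                stop("gene ", g$gene_id[i],
                     " not covered by any genotype segment")
            switch(ss$state[k], HOM_MAT = 1, HOM_PAT = 0, HET = 0.5)
        }, numeric(1))
    }

    if (length(state$forceSilenced))
        scale[g$gene_id %in% state$forceSilenced] <- leak

    # X-linked behaviour
    if (any(g$is_x)) {
        xi <- g$is_x & !g$is_xist
        xist <- g$is_xist
        if (state$sex %in% c("XY", "X0")) {
            # single (maternal) X, no X inactivation
            f[xi | xist] <- 1
            scale[xi] <- 0.5
            scale[xist] <- 0.01
        } else if (state$cellType == "EpiSC") {
            # post-XCI: one active X per cell; Xist marks the inactive X.
            # In PGA lines the allelic fraction is haplotype-driven and
            # already set above.
            if (state$origin != "PGA") {
                s <- state$xciSkew
                f[xi] <- s * leak + (1 - s) * (1 - leak)
                f[xist] <- s * (1 - leak) + (1 - s) * leak
            }
            scale[xi] <- 0.5
            scale[xist] <- 1
        } else {
            # XX ESC / early embryonic: both X active, Xist off
            if (state$origin != "PGA") f[xi | xist] <- 0.5
            scale[xist] <- 0.01
        }
    }

    if (!is.null(state$trisomy)) {
        on <- g$chrom == state$trisomy$chrom
        dm <- 1 + (state$trisomy$parent == "mat")
        dp <- 1 + (state$trisomy$parent == "pat")
        dose <- f[on] * dm + (1 - f[on]) * dp  # relative to the diploid dose 1
        f[on] <- f[on] * dm / dose
        scale[on] <- scale[on] * dose
    }
    data.frame(gene_id = g$gene_id, f_expected = f, scale = scale,
               stringsAsFactors = FALSE)
}

#' Simulate a per-sample allelic count table
#'
#' Generative inverse of the gene-level allelic calling: per gene the
#' total read count is Poisson with mean `depth` times the relative
#' abundance (state-scaled), maternal reads are beta-binomial around the
#' expected maternal fraction, and reads are spread multinomially over
#' the gene's exonic SNP sites.  Genes without exonic SNPs contribute no
#' rows.  Within homozygous segments of PGA genotypes no reads are ever
#' assigned to the absent haplotype.
#'
#' @param snps SNP map `data.frame` (defines the site universe).
#' @param genes a [GeneModels-class] object.
#' @param truth a [SimTruth-class] object with the gene table (and
#'   genotype segments for PGA states).
#' @param state a [cellStateConfig()] list.
#' @param sampleIdLabel sample label.
#' @param seed integer seed.
#' @return an [AllelicCounts-class] object.
#' @export
simulateSample <- function(snps, genes, truth, state = cellStateConfig(),
                           sampleIdLabel = "sim", seed = 1L) {
    set.seed(seed)
    g <- truthGenes(truth)
    imprinted <- g$class %in% c("MAT_EXPR", "PAT_EXPR", "BIASED")
    lossMask <- imprinted & runif(nrow(g)) > state$imprintFidelity
    ef <- expectedMatFraction(truth, state, lossMask = lossMask)
    mu <- state$depth * (g$abundance * ef$scale) / mean(g$abundance)
    totals <- rpois(nrow(g), mu)
    cmat <- .rbetabinom(nrow(g), totals, ef$f_expected,
                        state$overdispersion)

    st <- siteTable(genes)
    rows <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
        if (totals[i] == 0) next
        si <- st[st$gene_id == g$gene_id[i], , drop = FALSE]
        ns <- nrow(si)
        if (ns == 0) next
        read_site <- sample.int(ns, totals[i], replace = TRUE)
        mat_per <- tabulate(read_site[seq_len(cmat[i])], nbins = ns)
        tot_per <- tabulate(read_site, nbins = ns)
        keep <- tot_per > 0
        rows[[i]] <- data.frame(chrom = si$chrom[keep],
                                pos = si$pos[keep],
                                mat_count = mat_per[keep],
                                pat_count = tot_per[keep] - mat_per[keep],
                                stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    df <- if (length(rows))
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame(chrom = character(0), pos = numeric(0),
                    mat_count = numeric(0), pat_count = numeric(0))
    # overlapping genes cannot occur (placement is non-overlapping), but
    # aggregate defensively in case of shared sites
    if (nrow(df) && anyDuplicated(paste(df$chrom, df$pos))) {
        df <- aggregate(cbind(mat_count, pat_count) ~ chrom + pos,
                        data = df, FUN = sum)
    }
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    suppressWarnings(
        AllelicCounts(sampleIdLabel, df, chromLengths(truth)))
}

#' Simulate genotyping-grade allelic coverage along chromosomes
#'
#' Emulates the binned coverage the RNA-seq genotyper sees: per bin the
#' total allelic count is Poisson with mean `meanBinCoverage`, reads are
#' spread uniformly over the SNP sites of the bin, and each site's
#' maternal count follows its genotype state (all-maternal or
#' all-paternal in homozygous runs; beta-binomial around 0.5, with the
#' beta deviate shared per bin, in heterozygous runs).  Bins straddling
#' a crossover are mixed naturally because states are resolved per site.
#'
#' @param snps SNP map `data.frame`.
#' @param truth a [SimTruth-class] object with genotype segments.
#' @param meanBinCoverage expected allelic counts per bin (default 50).
#' @param binSizeMb bin size used for the coverage target (default 1).
#' @param overdispersion beta-binomial rho for heterozygous bins.
#' @param sampleIdLabel sample label.
#' @param seed integer seed.
#' @return an [AllelicCounts-class] object.
#' @export
simulateAllelicCoverage <- function(snps, truth, meanBinCoverage = 50,
                                    binSizeMb = 1, overdispersion = 0.01,
                                    sampleIdLabel = "simcov", seed = 1L) {
    set.seed(seed)
    size <- binSizeMb * 1e6
    segs <- truthSegments(truth)
    cl <- chromLengths(truth)
    out <- list()
    for (ch in names(cl)) {
        s <- snps[snps$chrom == ch, , drop = FALSE]
        if (nrow(s) == 0) next
        ss <- segs[segs$chrom == ch, , drop = FALSE]
        state <- ss$state[findInterval(s$pos, ss$start)]
        bin <- floor(s$pos / size)
        tot <- numeric(nrow(s))
        for (b in unique(bin)) {
            idx <- which(bin == b)
            nb <- rpois(1, meanBinCoverage)
            if (nb == 0) next
            tot[idx] <- tabulate(sample.int(length(idx), nb,
                                            replace = TRUE),
                                 nbins = length(idx))
        }
        mat <- numeric(nrow(s))
        hom_m <- state == "HOM_MAT"
        mat[hom_m] <- tot[hom_m]
        het <- which(state == "HET" & tot > 0)
        if (length(het)) {
            for (b in unique(bin[het])) {
                idx <- het[bin[het] == b]
                p <- if (overdispersion > 0)
                    rbeta(1, 0.5 * (1 - overdispersion) / overdispersion,
                          0.5 * (1 - overdispersion) / overdispersion)
                else 0.5
                mat[idx] <- rbinom(length(idx), tot[idx], p)
            }
        }
        keep <- tot > 0
        out[[ch]] <- data.frame(chrom = ch, pos = s$pos[keep],
                                mat_count = mat[keep],
                                pat_count = tot[keep] - mat[keep],
                                stringsAsFactors = FALSE)
    }
    df <- if (length(out))
        do.call(rbind, c(out, list(make.row.names = FALSE)))
    else data.frame(chrom = character(0), pos = numeric(0),
                    mat_count = numeric(0), pat_count = numeric(0))
    AllelicCounts(sampleIdLabel, df, cl)
}
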