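#' Derive per-stage child seeds from one master seed
#'
#' Deterministic fan-out so every pipeline stage and replicate has its
#' own reproducible stream; children stay below 2^31.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
childSeeds <- function(seed, n) {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a matched fertilized / PGA cohort
#'
#' Convenience wrapper: one genome, one SNP map, one gene universe, one
#' PGA genotype truth, then `nFert` fertilized and `nPga` PGA samples
#' drawn under a common cell state.
#'
#' @param nFert,nPga samples per group.
#' @param nGenes genes in the simulated universe.
#' @param depth expected reads per average gene.
#' @param chromLengths named numeric vector (bp).
#' @param snpDensity sites per bp.
#' @param state base [cellStateConfig()]; origin is overridden per group.
#' @param model [crossoverModel()] for the PGA genotype.
#' @param seed master seed.
#' @return list with `snps`, `genes`, `truthFert`, `truthPga`,
#'   `fert` and `pga` (lists of [AllelicCounts-class]), `catalog`
#'   (imprinted genes with `parent` codes).
#' @export
simulateCohort <- function(nFert = 2, nPga = 2, nGenes = 300,
                           depth = 200,
                           chromLengths = defaultChromLengths(lengthMb = 30),
                           snpDensity = 1 / 520,
                           state = cellStateConfig(cellType = "EpiSC"),
                           model = crossoverModel(nCrossoversRange = c(1, 3)),
                           seed = 1L) {
    seeds <- childSeeds(seed, 4 + nFert + nPga)
    snps <- makeSnpMap(chromLengths, snpDensity, seed = seeds[1])
    gm <- makeGeneModels(snps, chromLengths, nGenes = nGenes,
                         seed = seeds[2])
    pga_geno <- simulatePgaGenotype(chromLengths, model, seed = seeds[3])
    truthFert <- gm$truth
    truthFert@segments <- truthSegments(f1Genotype(chromLengths))
    truthPga <- gm$truth
    truthPga@segments <- truthSegments(pga_geno)
    truthPga@crossovers <- truthCrossovers(pga_geno)

    stFert <- state; stFert$origin <- "fertilized"; stFert$depth <- depth
    stPga <- state; stPga$origin <- "PGA"; stPga$depth <- depth
    fert <- lapply(seq_len(nFert), function(i)
        simulateSample(snps, gm$genes, truthFert, stFert,
                       sampleIdLabel = paste0("fert", i),
                       seed = seeds[4 + i]))
    pga <- lapply(seq_len(nPga), function(i)
        simulateSample(snps, gm$genes, truthPga, stPga,
                       sampleIdLabel = paste0("pga", i),
                       seed = seeds[4 + nFert + i]))
    names(fert) <- vapply(fert, sampleId, character(1))
    names(pga) <- vapply(pga, sampleId, character(1))
    tg <- truthGenes(gm$truth)
    catalog <- data.frame(
        gene_id = tg$gene_id[tg$class %in% c("MAT_EXPR", "PAT_EXPR")],
        parent = ifelse(tg$class[tg$class %in%
                                 c("MAT_EXPR", "PAT_EXPR")] == "MAT_EXPR",
                        "M", "P"),
        stringsAsFactors = FALSE)
    list(snps = snps, genes = gm$genes, truthFert = truthFert,
         truthPga = truthPga, fert = fert, pga = pga, catalog = catalog)
}

#' Benchmark breakpoint recovery on seeded PGA simulations
#'
#' Simulates `nReplicates` independent chromosomes with a mosaic PGA
#' genotype, genotyping-grade allelic coverage and 1 MB-resolution
#' genotyping, then scores called against true crossover breakpoints.
#'
#' @param nReplicates number of simulated chromosomes.
#' @param chromLengthMb chromosome length (MB).
#' @param model [crossoverModel()] (default 1--3 crossovers, 20 MB gap).
#' @param snpDensity sites per bp (default 1e-4, one per 10 kb).
#' @param meanBinCoverage expected allelic counts per informative 1 MB
#'   bin (default 50).
#' @param config [genotyperConfig()] used for the calls (default 1 MB,
#'   RNA thresholds).
#' @param overdispersion beta-binomial rho of the coverage simulation.
#' @param seed master seed.
#' @return list with `pooled` (a `"BreakpointAccuracy"` summary over all
#'   replicates) and `per_replicate` data.frame.
#' @export
benchmarkGenotyper <- function(nReplicates = 200, chromLengthMb = 100,
                               model = crossoverModel(
                                   nCrossoversRange = c(1, 3)),
                               snpDensity = 1e-4, meanBinCoverage = 50,
                               config = genotyperConfig(binSizeMb = 1,
                                                        mode = "rna"),
                               overdispersion = 0.01, seed = 1L) {
    seeds <- childSeeds(seed, 3 * nReplicates)
    cl <- c(chr1 = chromLengthMb * 1e6)
    pairs <- list(); per <- list()
    n_true <- n_called <- 0L
    for (r in seq_len(nReplicates)) {
        snps <- makeSnpMap(cl, snpDensity, seed = seeds[3 * r - 2])
        truth <- simulatePgaGenotype(cl, model, seed = seeds[3 * r - 1])
        cov <- simulateAllelicCoverage(snps, truth,
                                       meanBinCoverage = meanBinCoverage,
                                       binSizeMb = config$binSizeMb,
                                       overdispersion = overdispersion,
                                       sampleIdLabel = paste0("rep", r),
                                       seed = seeds[3 * r])
        map <- genotypeSample(cov, config)
        acc <- compareGenotypes(map, truth)
        n_true <- n_true + acc$n_true
        n_called <- n_called + acc$n_called
        if (nrow(acc$pairs)) {
            acc$pairs$replicate <- r
            pairs[[r]] <- acc$pairs
        }
        per[[r]] <- data.frame(replicate = r, n_true = acc$n_true,
                               n_called = acc$n_called,
                               n_matched = acc$n_matched,
                               n_exact = acc$n_exact,
                               mean_abs_error_mb = acc$mean_abs_error_mb)
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs)
        else data.frame(chrom = character(0), called = numeric(0),
                        true = numeric(0), abs_error_mb = numeric(0),
                        exact = logical(0), replicate = integer(0))
    nm <- nrow(pairs)
    pooled <- structure(list(
        n_true = n_true, n_called = n_called,
        n_matched = nm, n_exact = sum(pairs$exact),
        exact_fraction = if (nm) sum(pairs$exact) / nm else NA_real_,
        mean_abs_error_mb = if (nm) mean(pairs$abs_error_mb)
                            else NA_real_,
        pairs = pairs), class = "BreakpointAccuracy")
    list(pooled = pooled,
         per_replicate = do.call(rbind, per))
}

#' Run the full analysis over a sample sheet
#'
#' For every sample: read (or take) its allelic counts; PGA samples are
#' genotyped first and their gene calls restricted to heterozygous
#' regions; all samples get gene-level allelic calls and the expression
#' proxy.  Outputs are written under `outDir` together with a manifest
#' (config snapshot, input digests, seed, per-stage row counts).
#'
#' @param sampleSheet `data.frame` with columns `sample_id`,
#'   `counts_path` (or `NULL` paths when `countsList` is given),
#'   `class` (`cellline`/`embryonic`), `origin`
#'   (`fertilized`/`NT`/`PGA`), `sex`.
#' @param genes a [GeneModels-class] object.
#' @param config an [analysisConfig()] list.
#' @param outDir output directory (created); `NULL` skips writing.
#' @param countsList optional named list of [AllelicCounts-class]
#'   objects keyed by `sample_id`, bypassing file reads.
#' @return list with per-sample `calls`, `expression`, `genotypes`
#'   (PGA only) and the `manifest`.
#' @export
runEndToEnd <- function(sampleSheet, genes, config = analysisConfig(),
                        outDir = NULL, countsList = NULL) {
    need <- c("sample_id", "class", "origin", "sex")
    if (!all(need %in% names(sampleSheet)))
        stop("sample sheet must have columns: ",
             paste(need, collapse = ", "))
    if (!is.null(outDir))
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    calls <- list(); exprs <- list(); maps <- list(); digests <- list()
    for (i in seq_len(nrow(sampleSheet))) {
        sid <- sampleSheet$sample_id[i]
        x <- if (!is.null(countsList)) countsList[[sid]]
             else {
                 p <- sampleSheet$counts_path[i]
                 if (is.na(p) || !file.exists(p))
                     stop("stage read_counts: missing counts for sample ",
                          sid)
                 readCounts(p, sampleId = sid)
             }
        if (is.null(x))
            stop("stage read_counts: missing counts for sample ", sid)
        digests[[sid]] <- .digest_counts(x)
        map <- NULL
        if (sampleSheet$origin[i] == "PGA") {
            map <- genotypeSample(x, config$genotyper)
            maps[[sid]] <- map
        }
        cc <- callGenes(x, genes, config$expression)
        cc <- restrictToHet(cc, genes, map)
        calls[[sid]] <- cc
        exprs[[sid]] <- sampleExpression(x, genes)
        if (!is.null(outDir)) {
            writeGeneCalls(cc, file.path(outDir,
                                         paste0(sid, "_calls.tsv")))
            if (!is.null(map))
                writeSegments(map, file.path(outDir,
                                             paste0(sid, "_segments.bed")))
        }
    }
    manifest <- list(
        seed = config$seed,
        genotyper = unclass(config$genotyper),
        expression = unclass(config$expression),
        samples = lapply(seq_len(nrow(sampleSheet)), function(i) {
            sid <- sampleSheet$sample_id[i]
            list(sample_id = sid, class = sampleSheet$class[i],
                 origin = sampleSheet$origin[i],
                 sex = sampleSheet$sex[i],
                 counts_digest = digests[[sid]],
                 n_genes_called = sum(calls[[sid]]$status == "PASS"))
        }))
    if (!is.null(outDir))
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    list(calls = calls, expression = exprs, genotypes = maps,
         manifest = manifest)
}

# md5 of the serialized counts table (input digest for the manifest)
.digest_counts <- function(x) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeCounts(x, tf)
    unname(tools::md5sum(tf))
}
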