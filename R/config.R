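#' Genotyper thresholds
#'
#' All thresholds of the RNA-seq genotyping procedure, named and
#' overridable.  Defaults depend on the resolution and assay:
#' at 5 MB resolution bins with a summed allelic count <= 40 are labelled
#' insufficient, a trailing moving average over 4 qualifying bins smooths
#' the allelic percentage, and class boundaries are 31 / 78.5 %B6
#' (maternal).  At 1 MB resolution no smoothing is applied, bins are
#' included only when the summed count exceeds 10 (RNA) or 15 (DNA), and
#' the boundaries tighten to 15 / 85.
#'
#' @param binSizeMb bin size in MB, 5 or 1.
#' @param mode `"rna"` or `"dna"`; only affects the 1 MB count gate.
#' @param minBinCounts bins with `total <= minBinCounts` are labelled
#'   `INSUFFICIENT`.
#' @param maWindow moving-average window (qualifying bins); `0` disables
#'   smoothing.
#' @param pctLow,pctHigh class boundaries on the maternal percentage:
#'   `[0, pctLow)` paternal-homozygous, `[pctLow, pctHigh)` heterozygous,
#'   `[pctHigh, 100]` maternal-homozygous (lower-inclusive).
#' @param proximalRuleA,proximalRuleB `(n bins, fraction)` rules assigning
#'   the proximal genotype when at least `fraction` of the first `n`
#'   classified bins share one homozygous label.
#' @param hetRun the proximal genotype is heterozygous when more than
#'   `hetRun` consecutive classified bins at the chromosome start are
#'   heterozygous.
#' @param switchRun a breakpoint opens when more than `switchRun`
#'   consecutive classified bins lack the current segment label.
#' @param proximalShortRun at the very proximal end only, a run of at
#'   least this many consecutive classified bins of one other genotype
#'   also opens a breakpoint.
#' @param minSegmentMb segments of at most this many MB flanked by two
#'   segments of the same label are merged away (both breakpoints
#'   discarded).
#' @param imbalanceBand heterozygous chromosomes whose pooled maternal
#'   percentage falls outside this band are flagged as allelically
#'   imbalanced (aneuploidy screen).
#' @return a list of class `"GenotyperConfig"`.
#' @export
genotyperConfig <- function(binSizeMb = 5, mode = c("rna", "dna"),
                            minBinCounts = NULL, maWindow = NULL,
                            pctLow = NULL, pctHigh = NULL,
                            proximalRuleA = c(5, 0.8),
                            proximalRuleB = c(10, 0.6),
                            hetRun = 5, switchRun = 5,
                            proximalShortRun = 4, minSegmentMb = 15,
                            imbalanceBand = c(40, 60)) {
    mode <- match.arg(mode)
    stopifnot(binSizeMb %in% c(5, 1))
    if (binSizeMb == 5) {
        if (is.null(minBinCounts)) minBinCounts <- 40
        if (is.null(maWindow)) maWindow <- 4
        if (is.null(pctLow)) pctLow <- 31
        if (is.null(pctHigh)) pctHigh <- 78.5
    } else {
        if (is.null(minBinCounts))
            minBinCounts <- if (mode == "rna") 10 else 15
        if (is.null(maWindow)) maWindow <- 0
        if (is.null(pctLow)) pctLow <- 15
        if (is.null(pctHigh)) pctHigh <- 85
    }
    stopifnot(pctLow >= 0, pctLow < pctHigh, pctHigh <= 100,
              minBinCounts > 0, hetRun >= 1, switchRun >= 1,
              proximalShortRun >= 1, minSegmentMb > 0)
    structure(list(binSizeMb = binSizeMb, mode = mode,
                   minBinCounts = minBinCounts, maWindow = maWindow,
                   pctLow = pctLow, pctHigh = pctHigh,
                   proximalRuleA = proximalRuleA,
                   proximalRuleB = proximalRuleB,
                   hetRun = hetRun, switchRun = switchRun,
                   proximalShortRun = proximalShortRun,
                   minSegmentMb = minSegmentMb,
                   imbalanceBand = imbalanceBand),
              class = "GenotyperConfig")
}

#' Gene-level allelic expression filters
#'
#' @param minGeneCounts genes need a summed allelic coverage strictly
#'   greater than this to be called (default 9).
#' @param maxStdem maximum standard error of the mean of per-site
#'   maternal fractions (default 0.15; bypassed for single-site genes).
#' @param minSiteCov a site enters the consistency statistic when at
#'   least one allele reaches this coverage (default 3).
#' @param siteRule `"max"` (default; coverage >= minSiteCov from either
#'   allele means max(mat, pat) >= minSiteCov) or `"sum"`.
#' @param siteGateGeneSums logical; if `TRUE` the per-site coverage rule
#'   also gates the gene-level sums (default `FALSE`: all exonic sites
#'   are summed, the gate applies only to the consistency statistic).
#' @param cohortMinCellline,cohortMinEmbryo per-sample total coverage a
#'   gene must exceed in every cell-line / embryonic sample to enter the
#'   global analysis (defaults 40 and 200).
#' @param biasThreshold allelic bias is called when one allele contributes
#'   strictly more than this fraction (default 0.80; exactly 0.80 is
#'   biallelic).
#' @param xciReferenceMaxFold X-linked genes enter the X-inactivation
#'   analysis only when their allelic bias in the designated balanced
#'   reference sample is below this fold (default 4).
#' @return a list of class `"ExpressionFilterConfig"`.
#' @export
expressionFilterConfig <- function(minGeneCounts = 9, maxStdem = 0.15,
                                   minSiteCov = 3,
                                   siteRule = c("max", "sum"),
                                   siteGateGeneSums = FALSE,
                                   cohortMinCellline = 40,
                                   cohortMinEmbryo = 200,
                                   biasThreshold = 0.80,
                                   xciReferenceMaxFold = 4) {
    siteRule <- match.arg(siteRule)
    stopifnot(minGeneCounts > 0, maxStdem > 0, minSiteCov > 0,
              biasThreshold > 0.5, biasThreshold < 1,
              cohortMinCellline > 0, cohortMinEmbryo > 0,
              xciReferenceMaxFold > 1)
    structure(list(minGeneCounts = minGeneCounts, maxStdem = maxStdem,
                   minSiteCov = minSiteCov, siteRule = siteRule,
                   siteGateGeneSums = siteGateGeneSums,
                   cohortMinCellline = cohortMinCellline,
                   cohortMinEmbryo = cohortMinEmbryo,
                   biasThreshold = biasThreshold,
                   xciReferenceMaxFold = xciReferenceMaxFold),
              class = "ExpressionFilterConfig")
}

#' Crossover model for simulated PGA genotypes
#'
#' @param nCrossoversRange integer range of crossovers per chromosome
#'   (inclusive; default 0 to 3).
#' @param minGapMb minimum distance between crossovers on a chromosome
#'   (MB; default 20).
#' @return a list of class `"CrossoverModel"`.
#' @export
crossoverModel <- function(nCrossoversRange = c(0L, 3L), minGapMb = 20) {
    stopifnot(length(nCrossoversRange) == 2,
              nCrossoversRange[1] >= 0,
              nCrossoversRange[2] >= nCrossoversRange[1],
              minGapMb > 0)
    structure(list(nCrossoversRange = as.integer(nCrossoversRange),
                   minGapMb = minGapMb),
              class = "CrossoverModel")
}

#' Cell-state configuration for the sample simulator
#'
#' Describes the biological state whose allelic signature is simulated:
#' cell type, derivation origin, sex, imprint retention, X-inactivation
#' skew, residual expression of silenced alleles, sequencing depth and
#' allelic overdispersion.
#'
#' @param cellType `"embryonic"`, `"ESC"` or `"EpiSC"`.
#' @param origin `"fertilized"`, `"NT"` or `"PGA"`.
#' @param sex `"XX"`, `"XY"` or `"X0"`.
#' @param imprintFidelity probability that an imprinted gene retains its
#'   parent-of-origin expression (per-gene Bernoulli; 1 = faithful,
#'   0 = complete loss of imprinting, as seen in serum ESC lines).
#' @param xciSkew fraction of cells carrying a maternal inactive X
#'   (XX EpiSC only; 0.5 = balanced random X inactivation, 1 = fully
#'   skewed / clonal).
#' @param paternalLeak residual expression fraction of a silenced allele
#'   (default 0.02).
#' @param depth expected total allelic read count for a gene of average
#'   abundance.
#' @param overdispersion beta-binomial correlation parameter rho for
#'   allelic read sampling (default 0.01; 0 = pure binomial).
#' @param trisomy optional `list(chrom =, parent = "mat"|"pat")` adding
#'   one extra parental copy of a chromosome.
#' @param forceSilenced gene ids silenced irrespective of class (models
#'   the aberrant Rian/Meg3-type silencing of some NT lines).
#' @return a list of class `"CellStateConfig"`.
#' @export
cellStateConfig <- function(cellType = c("EpiSC", "ESC", "embryonic"),
                            origin = c("fertilized", "NT", "PGA"),
                            sex = c("XX", "XY", "X0"),
                            imprintFidelity = 1, xciSkew = 0.5,
                            paternalLeak = 0.02, depth = 200,
                            overdispersion = 0.01, trisomy = NULL,
                            forceSilenced = character(0)) {
    cellType <- match.arg(cellType)
    origin <- match.arg(origin)
    sex <- match.arg(sex)
    stopifnot(imprintFidelity >= 0, imprintFidelity <= 1,
              xciSkew >= 0, xciSkew <= 1,
              paternalLeak >= 0, paternalLeak < 0.5,
              depth > 0, overdispersion >= 0, overdispersion < 1)
    if (!is.null(trisomy))
        stopifnot(is.list(trisomy), !is.null(trisomy$chrom),
                  trisomy$parent %in% c("mat", "pat"))
    structure(list(cellType = cellType, origin = origin, sex = sex,
                   imprintFidelity = imprintFidelity, xciSkew = xciSkew,
                   paternalLeak = paternalLeak, depth = depth,
                   overdispersion = overdispersion, trisomy = trisomy,
                   forceSilenced = forceSilenced),
              class = "CellStateConfig")
}

#' Bundle of all analysis thresholds
#'
#' @param genotyper a [genotyperConfig()] list.
#' @param expression an [expressionFilterConfig()] list.
#' @param seed integer seed used by pipeline helpers.
#' @return a list of class `"AnalysisConfig"`.
#' @export
analysisConfig <- function(genotyper = genotyperConfig(binSizeMb = 1),
                           expression = expressionFilterConfig(),
                           seed = 1L) {
    structure(list(genotyper = genotyper, expression = expression,
                   seed = as.integer(seed)),
              class = "AnalysisConfig")
}

#' Read an analysis configuration from YAML
#'
#' Flat keys under `genotyper:` and `expression:` override the
#' corresponding defaults of [genotyperConfig()] and
#' [expressionFilterConfig()].
#'
#' @param path YAML file.
#' @return an `"AnalysisConfig"` list.
#' @export
readAnalysisConfig <- function(path) {
    y <- yaml::read_yaml(path)
    gt <- do.call(genotyperConfig, as.list(y$genotyper))
    ex <- do.call(expressionFilterConfig, as.list(y$expression))
    analysisConfig(genotyper = gt, expression = ex,
                   seed = if (is.null(y$seed)) 1L else y$seed)
}

#' @exportS3Method base::print
print.GenotyperConfig <- function(x, ...) {
    cat(sprintf("GenotyperConfig: %g MB bins (%s)\n", x$binSizeMb, x$mode))
    cat(sprintf("  insufficient if total <= %g; boundaries [0,%g) / [%g,%g) / [%g,100]\n",
                x$minBinCounts, x$pctLow, x$pctLow, x$pctHigh, x$pctHigh))
    cat(sprintf("  smoothing window %g; switch run > %g; proximal short run >= %g; min segment %g MB\n",
                x$maWindow, x$switchRun, x$proximalShortRun, x$minSegmentMb))
    invisible(x)
}
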