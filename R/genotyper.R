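#' Bin allelic counts along chromosomes
#'
#' Sums maternal and paternal counts in consecutive genomic bins and
#' computes the maternal percentage `100 * mat / (mat + pat)` per bin.
#' Every bin of every declared chromosome is present, including
#' zero-count bins; bin spans are half-open `[i*size, (i+1)*size)` so a
#' site at exactly a bin boundary belongs to the following bin.
#'
#' @param x an [AllelicCounts-class] object.
#' @param binSizeMb bin size in MB.
#' @return `data.frame` with columns `chrom`, `bin` (0-based), `start`,
#'   `end`, `mat_count`, `pat_count`, `total`, `pct_mat` (`NA` when the
#'   bin is empty).
#' @export
binCounts <- function(x, binSizeMb = 5) {
    stopifnot(is(x, "AllelicCounts"), binSizeMb > 0)
    size <- binSizeMb * 1e6
    cl <- chromLengths(x)
    df <- countsTable(x)
    out <- lapply(names(cl), function(ch) {
        len <- cl[[ch]]
        nb <- max(1L, ceiling(len / size))
        mat <- pat <- numeric(nb)
        d <- df[df$chrom == ch, , drop = FALSE]
        if (nrow(d)) {
            if (any(d$pos >= len))
                stop("site beyond declared length of ", ch)
            idx <- floor(d$pos / size) + 1L
            mat <- as.numeric(tapply(d$mat_count, factor(idx, levels = seq_len(nb)), sum))
            pat <- as.numeric(tapply(d$pat_count, factor(idx, levels = seq_len(nb)), sum))
            mat[is.na(mat)] <- 0
            pat[is.na(pat)] <- 0
        }
        tot <- mat + pat
        data.frame(chrom = ch, bin = seq_len(nb) - 1L,
                   start = (seq_len(nb) - 1L) * size,
                   end = pmin(seq_len(nb) * size, len),
                   mat_count = mat, pat_count = pat, total = tot,
                   pct_mat = ifelse(tot > 0, 100 * mat / tot, NA_real_),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Smooth binned allelic percentages with a trailing moving average
#'
#' For each bin whose total exceeds the coverage gate, the smoothed
#' percentage is the mean of `pct_mat` over the trailing window of up to
#' `maWindow` qualifying bins ending at it (window truncated at the
#' chromosome start; non-qualifying bins are skipped and receive `NA`).
#'
#' @param bins output of [binCounts()].
#' @param config a [genotyperConfig()] list (uses `minBinCounts` and
#'   `maWindow`).
#' @return `bins` with an added `pct_smoothed` column.
#' @export
smoothBins <- function(bins, config = genotyperConfig()) {
    bins$pct_smoothed <- NA_real_
    if (config$maWindow < 1) {
        bins$pct_smoothed <- bins$pct_mat
        return(bins)
    }
    for (ch in unique(bins$chrom)) {
        i <- which(bins$chrom == ch)
        q <- i[bins$total[i] > config$minBinCounts]
        if (!length(q)) next
        sm <- vapply(seq_along(q), function(k) {
            w <- q[max(1L, k - config$maWindow + 1L):k]
            mean(bins$pct_mat[w])
        }, numeric(1))
        bins$pct_smoothed[q] <- sm
    }
    bins
}

#' Classify bins into genotype labels
#'
#' Bins with `total <= minBinCounts` are `INSUFFICIENT`; the remainder
#' are labelled by the (smoothed, when a moving average is configured)
#' maternal percentage with lower-inclusive boundaries:
#' `[0, pctLow)` -> `PAT_HOM`, `[pctLow, pctHigh)` -> `HET`,
#' `[pctHigh, 100]` -> `MAT_HOM`.
#'
#' @param bins output of [binCounts()] (run through [smoothBins()] when
#'   the configuration uses a moving average).
#' @param config a [genotyperConfig()] list.
#' @return `bins` with an added `label` column.
#' @export
classifyBins <- function(bins, config = genotyperConfig()) {
    if (config$maWindow >= 1 && is.null(bins$pct_smoothed))
        bins <- smoothBins(bins, config)
    p <- if (config$maWindow >= 1) bins$pct_smoothed else bins$pct_mat
    lab <- rep("INSUFFICIENT", nrow(bins))
    ok <- bins$total > config$minBinCounts & !is.na(p)
    lab[ok & p < config$pctLow] <- "PAT_HOM"
    lab[ok & p >= config$pctLow & p < config$pctHigh] <- "HET"
    lab[ok & p >= config$pctHigh] <- "MAT_HOM"
    bins$label <- lab
    bins
}

#' Assign the proximal (centromeric) genotype of a chromosome
#'
#' Applies, in order and first match wins, to the classified
#' (non-`INSUFFICIENT`) bins ordered proximal to distal:
#' (1) at least 80\% of the first 5 bins share one homozygous label;
#' (2) at least 60\% of the first 10 bins share one homozygous label;
#' (3) more than 5 consecutive heterozygous bins at the start.
#'
#' @param labels character vector of bin labels, proximal to distal
#'   (`INSUFFICIENT` bins are skipped from all counting).
#' @param config a [genotyperConfig()] list.
#' @return one of `"MAT_HOM"`, `"PAT_HOM"`, `"HET"`, `"UNASSIGNED"`.
#' @export
assignProximalGenotype <- function(labels, config = genotyperConfig(binSizeMb = 1)) {
    cls <- labels[labels != "INSUFFICIENT"]
    m <- length(cls)
    if (m < config$proximalRuleA[1]) {
        warning("fewer than ", config$proximalRuleA[1],
                " classified bins; genotype unassigned")
        return("UNASSIGNED")
    }
    .proximal_assign(cls, config)
}

# rules on an already-filtered classified label vector
.proximal_assign <- function(cls, config) {
    m <- length(cls)
    n1 <- config$proximalRuleA[1]; f1 <- config$proximalRuleA[2]
    n2 <- config$proximalRuleB[1]; f2 <- config$proximalRuleB[2]
    if (m < n1) return("UNASSIGNED")
    first1 <- cls[seq_len(n1)]
    for (L in c("MAT_HOM", "PAT_HOM"))
        if (sum(first1 == L) >= f1 * n1) return(L)
    if (m >= n2) {
        first2 <- cls[seq_len(n2)]
        for (L in c("MAT_HOM", "PAT_HOM"))
            if (sum(first2 == L) >= f2 * n2) return(L)
    }
    run <- 0L
    while (run < m && cls[run + 1L] == "HET") run <- run + 1L
    if (run > config$hetRun) return("HET")
    "UNASSIGNED"
}

# Core segmentation on a label vector (one chromosome).
# Returns bin-index segments and breakpoints (1-based bin indices).
.segment_labels <- function(labels, config) {
    n <- length(labels)
    cidx <- which(labels != "INSUFFICIENT")
    m <- length(cidx)
    unassigned <- list(
        assigned = "UNASSIGNED",
        segments = data.frame(start_bin = 1L, end_bin = n,
                              label = "UNASSIGNED",
                              stringsAsFactors = FALSE),
        breakpoints = data.frame(bin = integer(0),
                                 left_label = character(0),
                                 right_label = character(0),
                                 stringsAsFactors = FALSE))
    if (m < config$proximalRuleA[1]) return(unassigned)
    cls <- labels[cidx]
    g0 <- .proximal_assign(cls, config)
    if (g0 == "UNASSIGNED") return(unassigned)

    seg_labels <- g0
    bp_bins <- integer(0)
    cur <- g0
    first_seg <- TRUE
    j <- 1L
    while (j <= m) {
        if (cls[j] == cur) { j <- j + 1L; next }
        k <- j
        while (k < m && cls[k + 1L] != cur) k <- k + 1L
        runlen <- k - j + 1L
        lead <- 1L
        while (j + lead <= k && cls[j + lead] == cls[j]) lead <- lead + 1L
        trigA <- runlen > config$switchRun
        trigB <- first_seg && lead >= config$proximalShortRun
        newlab <- "UNASSIGNED"
        if (trigA) {
            newlab <- .proximal_assign(cls[j:m], config)
            if (newlab == "UNASSIGNED" && lead >= config$proximalShortRun)
                newlab <- cls[j]
        } else if (trigB) {
            newlab <- cls[j]
        }
        if (newlab != "UNASSIGNED" && newlab != cur) {
            bp_bins <- c(bp_bins, cidx[j])
            seg_labels <- c(seg_labels, newlab)
            cur <- newlab
            first_seg <- FALSE
            j <- j + 1L
        } else {
            j <- k + 1L
        }
    }

    seg_start <- c(1L, bp_bins)
    seg_end <- c(bp_bins - 1L, n)
    segs <- data.frame(start_bin = seg_start, end_bin = seg_end,
                       label = seg_labels, stringsAsFactors = FALSE)
    segs <- .merge_short_segments(segs, config)
    bp <- if (nrow(segs) > 1)
        data.frame(bin = segs$start_bin[-1],
                   left_label = segs$label[-nrow(segs)],
                   right_label = segs$label[-1],
                   stringsAsFactors = FALSE)
    else
        data.frame(bin = integer(0), left_label = character(0),
                   right_label = character(0), stringsAsFactors = FALSE)
    list(assigned = g0, segments = segs, breakpoints = bp)
}

# One left-to-right pass discarding breakpoints around segments of at
# most minSegmentMb whose two flanks share a label; merged segments are
# not re-examined.
.merge_short_segments <- function(segs, config) {
    i <- 2L
    while (i <= nrow(segs) - 1L) {
        len_mb <- (segs$end_bin[i] - segs$start_bin[i] + 1L) *
            config$binSizeMb
        if (len_mb <= config$minSegmentMb &&
            segs$label[i - 1L] == segs$label[i + 1L]) {
            segs$end_bin[i - 1L] <- segs$end_bin[i + 1L]
            segs <- segs[-c(i, i + 1L), , drop = FALSE]
        } else {
            i <- i + 1L
        }
    }
    rownames(segs) <- NULL
    segs
}

#' Call crossover breakpoints on one chromosome
#'
#' Scans the classified bins distally from the assigned proximal
#' genotype.  A breakpoint opens where more than `switchRun` consecutive
#' classified bins lack the current segment label (or, at the very
#' proximal end only, where at least `proximalShortRun` consecutive bins
#' share one other genotype); the new segment label is re-derived with
#' the proximal-assignment rules from the breakpoint onward.  A final
#' left-to-right pass discards breakpoints flanking segments of at most
#' `minSegmentMb` whose neighbours share a label.  The breakpoint
#' coordinate is the start of the first bin of the new segment.
#'
#' @param bins classified bins of a single chromosome (one chromosome of
#'   the output of [classifyBins()]).
#' @param config a [genotyperConfig()] list.
#' @return list with `segments` (`chrom`, `start`, `end`, `label`,
#'   `mean_pct`) and `breakpoints` (`chrom`, `pos`, `left_label`,
#'   `right_label`), coordinates in bp.
#' @export
callBreakpoints <- function(bins, config = genotyperConfig(binSizeMb = 1)) {
    stopifnot(length(unique(bins$chrom)) == 1, !is.null(bins$label))
    ch <- bins$chrom[1]
    res <- .segment_labels(bins$label, config)
    segs <- res$segments
    mean_pct <- vapply(seq_len(nrow(segs)), function(i) {
        r <- segs$start_bin[i]:segs$end_bin[i]
        tot <- sum(bins$total[r])
        if (tot > 0) 100 * sum(bins$mat_count[r]) / tot else NA_real_
    }, numeric(1))
    segments <- data.frame(chrom = ch,
                           start = bins$start[segs$start_bin],
                           end = bins$end[segs$end_bin],
                           label = segs$label,
                           mean_pct = mean_pct,
                           stringsAsFactors = FALSE)
    bp <- res$breakpoints
    breakpoints <- data.frame(chrom = rep(ch, nrow(bp)),
                              pos = bins$start[bp$bin],
                              left_label = bp$left_label,
                              right_label = bp$right_label,
                              stringsAsFactors = FALSE)
    list(segments = segments, breakpoints = breakpoints)
}

#' Genotype a sample from its allelic count table
#'
#' Composition of [binCounts()], [smoothBins()], [classifyBins()] and
#' [callBreakpoints()] over all chromosomes, plus a chromosome-level
#' allelic-imbalance screen: chromosomes called heterozygous whose pooled
#' maternal percentage over heterozygous bins falls outside the
#' configured band (default 40--60\%) are flagged, the signature of an
#' unbalanced parental copy number such as a trisomy.
#'
#' @param x an [AllelicCounts-class] object.
#' @param config a [genotyperConfig()] list.
#' @return a [GenotypeMap-class] object.
#' @export
genotypeSample <- function(x, config = genotyperConfig()) {
    bins <- binCounts(x, config$binSizeMb)
    if (config$maWindow >= 1) bins <- smoothBins(bins, config)
    bins <- classifyBins(bins, config)
    segl <- list(); bpl <- list(); imb <- list()
    for (ch in names(chromLengths(x))) {
        b <- bins[bins$chrom == ch, , drop = FALSE]
        res <- suppressWarnings(callBreakpoints(b, config))
        segl[[ch]] <- res$segments
        bpl[[ch]] <- res$breakpoints
        het <- b$label == "HET"
        tot <- sum(b$total[het])
        pct <- if (tot > 0) 100 * sum(b$mat_count[het]) / tot else NA_real_
        imb[[ch]] <- data.frame(
            chrom = ch, het_pct_mat = pct,
            flagged = !is.na(pct) &&
                (pct < config$imbalanceBand[1] ||
                 pct > config$imbalanceBand[2]),
            stringsAsFactors = FALSE)
    }
    new("GenotypeMap", sampleId = sampleId(x),
        binSizeMb = config$binSizeMb, bins = bins,
        segments = do.call(rbind, c(segl, list(make.row.names = FALSE))),
        breakpoints = do.call(rbind, c(bpl, list(make.row.names = FALSE))),
        imbalance = do.call(rbind, c(imb, list(make.row.names = FALSE))))
}

#' Informative heterozygous regions of a genotype map
#'
#' Union of heterozygous segments; chromosomes with an unassigned
#' genotype are excluded entirely (conservative: nothing on them can be
#' used for allele-specific calls).
#'
#' @param map a [GenotypeMap-class] object.
#' @return `data.frame` with `chrom`, `start`, `end` (bp, half-open).
#' @export
heterozygousRegions <- function(map) {
    s <- genotypeSegments(map)
    una <- unique(s$chrom[s$label == "UNASSIGNED"])
    if (length(una))
        message("excluding unassigned chromosome(s): ",
                paste(una, collapse = ", "))
    out <- s[s$label == "HET" & !(s$chrom %in% una),
             c("chrom", "start", "end"), drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Score called breakpoints against a reference
#'
#' Breakpoints are paired 1:1 per chromosome by greedy nearest distance.
#' A matched pair is exact when both positions fall in the same bin of
#' `exactBinMb` MB.  `exact_fraction` is the exact share of matched
#' pairs and `mean_abs_error_mb` the mean absolute offset over matched
#' pairs.
#'
#' @param called a [GenotypeMap-class] object.
#' @param reference a [GenotypeMap-class] or [SimTruth-class] object.
#' @param exactBinMb bin size defining an exact match (default 1).
#' @return a list of class `"BreakpointAccuracy"`: `n_true`, `n_called`,
#'   `n_matched`, `n_exact`, `exact_fraction`, `mean_abs_error_mb`, and
#'   a `pairs` data.frame.
#' @export
compareGenotypes <- function(called, reference, exactBinMb = 1) {
    cb <- genotypeBreakpoints(called)
    tb <- if (is(reference, "SimTruth")) truthCrossovers(reference)
          else genotypeBreakpoints(reference)
    chroms <- union(unique(cb$chrom), unique(tb$chrom))
    pairs <- list()
    for (ch in chroms) {
        cc <- cb$pos[cb$chrom == ch]
        tt <- tb$pos[tb$chrom == ch]
        while (length(cc) && length(tt)) {
            d <- abs(outer(cc, tt, "-"))
            w <- which(d == min(d), arr.ind = TRUE)[1, ]
            pairs[[length(pairs) + 1L]] <- data.frame(
                chrom = ch, called = cc[w[1]], true = tt[w[2]],
                abs_error_mb = abs(cc[w[1]] - tt[w[2]]) / 1e6,
                exact = floor(cc[w[1]] / (exactBinMb * 1e6)) ==
                    floor(tt[w[2]] / (exactBinMb * 1e6)),
                stringsAsFactors = FALSE)
            cc <- cc[-w[1]]
            tt <- tt[-w[2]]
        }
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs)
        else data.frame(chrom = character(0), called = numeric(0),
                        true = numeric(0), abs_error_mb = numeric(0),
                        exact = logical(0))
    n_matched <- nrow(pairs)
    structure(list(
        n_true = nrow(tb), n_called = nrow(cb),
        n_matched = n_matched, n_exact = sum(pairs$exact),
        exact_fraction = if (n_matched) sum(pairs$exact) / n_matched
                         else NA_real_,
        mean_abs_error_mb = if (n_matched) mean(pairs$abs_error_mb)
                            else NA_real_,
        pairs = pairs), class = "BreakpointAccuracy")
}

#' @exportS3Method base::print
print.BreakpointAccuracy <- function(x, ...) {
    cat(sprintf("BreakpointAccuracy: %d true, %d called, %d matched\n",
                x$n_true, x$n_called, x$n_matched))
    cat(sprintf("  exact-bin matches: %d (%.1f%%); mean |error| %.2f MB\n",
                x$n_exact, 100 * x$exact_fraction, x$mean_abs_error_mb))
    invisible(x)
}
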