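# Brute-force re-derivation of the published genotyping rules, written
# independently of the package internals: explicit position-by-position
# scans, no shared helpers.  Operates on a plain label vector and
# returns the segment labels per bin plus breakpoint bin indices.

oracle_assign <- function(v, cfg) {
    if (length(v) < cfg$proximalRuleA[1]) return("UNASSIGNED")
    for (L in c("MAT_HOM", "PAT_HOM"))
        if (mean(v[seq_len(cfg$proximalRuleA[1])] == L) >=
            cfg$proximalRuleA[2]) return(L)
    if (length(v) >= cfg$proximalRuleB[1])
        for (L in c("MAT_HOM", "PAT_HOM"))
            if (mean(v[seq_len(cfg$proximalRuleB[1])] == L) >=
                cfg$proximalRuleB[2]) return(L)
    r <- rle(v)
    if (r$values[1] == "HET" && r$lengths[1] > cfg$hetRun) return("HET")
    "UNASSIGNED"
}

oracle_segment <- function(labels, cfg) {
    cid <- which(labels != "INSUFFICIENT")
    una <- list(assigned = "UNASSIGNED",
                labels = rep("UNASSIGNED", length(labels)),
                breakpoints = integer(0))
    if (length(cid) < cfg$proximalRuleA[1]) return(una)
    cls <- labels[cid]
    g0 <- oracle_assign(cls, cfg)
    if (g0 == "UNASSIGNED") return(una)

    m <- length(cls)
    bp <- integer(0)       # indices into cls (first bin of new segment)
    lab <- g0
    cur <- g0
    i <- 1
    while (i <= m) {
        if (cls[i] == cur) { i <- i + 1; next }
        # length of the run of classified bins differing from cur
        run <- 0
        while (i + run <= m && cls[i + run] != cur) run <- run + 1
        # leading stretch of one identical label inside the run
        lead <- 1
        while (lead < run && cls[i + lead] == cls[i]) lead <- lead + 1
        fired <- FALSE
        newlab <- "UNASSIGNED"
        if (run > cfg$switchRun) {
            fired <- TRUE
            newlab <- oracle_assign(cls[i:m], cfg)
            if (newlab == "UNASSIGNED" && lead >= cfg$proximalShortRun)
                newlab <- cls[i]
        } else if (length(bp) == 0 && lead >= cfg$proximalShortRun) {
            fired <- TRUE
            newlab <- cls[i]
        }
        if (fired && newlab != "UNASSIGNED" && newlab != cur) {
            bp <- c(bp, i)
            lab <- c(lab, newlab)
            cur <- newlab
            i <- i + 1
        } else {
            i <- i + run
        }
    }
    # discard breakpoints around runs of <= minSegmentMb with equal
    # flanks, one pass left to right
    starts <- c(1, bp)
    ends <- c(bp - 1, m)
    k <- 2
    while (k <= length(starts) - 1) {
        # segment width in original bins: from its first bin to the bin
        # before the next segment's first bin
        seg_bins <- if (k < length(starts))
            cid[starts[k + 1]] - cid[starts[k]]
        else length(labels) - cid[starts[k]] + 1
        if (seg_bins * cfg$binSizeMb <= cfg$minSegmentMb &&
            lab[k - 1] == lab[k + 1]) {
            starts <- starts[-c(k, k + 1)]
            ends <- ends[-c(k - 1, k)]
            lab <- lab[-c(k, k + 1)]
        } else k <- k + 1
    }
    out <- rep(NA_character_, length(labels))
    for (k in seq_along(starts)) {
        from <- if (k == 1) 1 else cid[starts[k]]
        to <- if (k == length(starts)) length(labels)
              else cid[starts[k + 1]] - 1
        out[from:to] <- lab[k]
    }
    list(assigned = g0, labels = out,
         breakpoints = if (length(starts) > 1) cid[starts[-1]]
                       else integer(0))
}

# package-side segmentation on a raw label vector, for comparison
pkg_segment_bins <- function(labels, cfg) {
    n <- length(labels)
    bins <- data.frame(chrom = "c", bin = seq_len(n) - 1L,
                       start = (seq_len(n) - 1) * cfg$binSizeMb * 1e6,
                       end = seq_len(n) * cfg$binSizeMb * 1e6,
                       mat_count = 0, pat_count = 0, total = 0,
                       pct_mat = NA_real_, label = labels,
                       stringsAsFactors = FALSE)
    res <- callBreakpoints(bins, cfg)
    lab <- rep(NA_character_, n)
    for (i in seq_len(nrow(res$segments))) {
        from <- res$segments$start[i] / (cfg$binSizeMb * 1e6) + 1
        to <- res$segments$end[i] / (cfg$binSizeMb * 1e6)
        lab[from:to] <- res$segments$label[i]
    }
    list(labels = lab,
         breakpoints = res$breakpoints$pos / (cfg$binSizeMb * 1e6) + 1)
}

random_label_seq <- function(n, p_ins = 0.1) {
    sample(c("MAT_HOM", "HET", "PAT_HOM", "INSUFFICIENT"), n,
           replace = TRUE, prob = c((1 - p_ins) * 0.35,
                                    (1 - p_ins) * 0.3,
                                    (1 - p_ins) * 0.35, p_ins))
}
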