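#' Two-sided Wilcoxon rank-sum test with midrank ties
#'
#' Computes the rank-sum statistic of the first sample (midranks across the
#' pooled data) and a two-sided p-value: by exhaustive permutation
#' enumeration when the smaller sample has at most `exactMax` observations
#' (exact even under ties), and by the normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param a,b numeric samples (each of size >= 1).
#' @param exactMax exact enumeration is used when `min(length(a),
#'   length(b)) <= exactMax` (and the enumeration is tractable).
#' @return list: `statistic` (rank sum of `a`), `p_value`, `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
wilcoxonRankSum <- function(a, b, exactMax = 8L) {
    if (!length(a) || !length(b)) stopf("both samples must be non-empty")
    na <- length(a); nb <- length(b); N <- na + nb
    r <- rank(c(a, b))                      # midranks
    w <- sum(r[seq_len(na)])

    useExact <- min(na, nb) <= exactMax && N <= 60
    if (useExact) {
        # permutation distribution of the smaller sample's rank sum,
        # counted by dynamic programming over doubled midranks (integers)
        m <- min(na, nb)
        r2 <- as.integer(round(2 * r))
        maxS <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
        ways <- matrix(0, m + 1L, maxS + 1L)
        ways[1L, 1L] <- 1
        for (x in r2) {
            for (k in m:1) {
                ways[k + 1L, (x + 1L):(maxS + 1L)] <-
                    ways[k + 1L, (x + 1L):(maxS + 1L)] +
                    ways[k, seq_len(maxS + 1L - x)]
            }
        }
        cnt <- ways[m + 1L, ]
        tot <- choose(N, m)
        obs2 <- round(2 * (if (na <= nb) w else sum(r) - w))
        sums2 <- 0:maxS
        pLe <- sum(cnt[sums2 <= obs2 + 1e-9]) / tot
        pGe <- sum(cnt[sums2 >= obs2 - 1e-9]) / tot
        p <- min(1, 2 * min(pLe, pGe))
        return(list(statistic = w, p_value = p, method = "exact"))
    }

    mu <- na * (N + 1) / 2
    ties <- table(r)
    tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
    v <- na * nb / 12 * ((N + 1) - tieAdj)
    if (v <= 0)
        return(list(statistic = w, p_value = 1, method = "normal"))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
    list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal")
}

#' Compare burst-property distributions between conditions
#'
#' For each burst metric (total output, burst amplitude, burst duration,
#' burst frequency), reports the per-condition median, the median relative
#' to the control condition, and a two-sided Wilcoxon rank-sum test of each
#' condition against the control. Nuclei with zero bursts contribute to the
#' total-output and burst-frequency metrics but are excluded from amplitude
#' and duration, where those properties are undefined.
#'
#' @param summaries data.frame: the per-nucleus `summary` table of
#'   [summarizeBursts()] with an added `condition` column (one row per
#'   nucleus).
#' @param control name of the control condition.
#' @return data.frame: `metric`, `condition`, `n`, `median`,
#'   `median_ratio` (vs control), `statistic`, `p_value`, `p_adj`
#'   (Benjamini-Hochberg across all non-control tests).
#' @export
compareConditions <- function(summaries, control) {
    need <- c("condition", "n_bursts", "mean_amplitude", "mean_duration_s",
              "total_output")
    miss <- setdiff(need, names(summaries))
    if (length(miss))
        stopf("'summaries' lacks column(s): %s", paste(miss, collapse = ", "))
    conds <- unique(summaries$condition)
    if (!(control %in% conds))
        stopf("control condition '%s' not present", control)
    if (length(conds) < 2L)
        stopf("need at least two conditions")
    for (cn in conds)
        if (!nrow(summaries[summaries$condition == cn, ]))
            stopf("condition '%s' is empty", cn)

    metrics <- list(
        total_output = function(d) d$total_output,
        amplitude = function(d) d$mean_amplitude[!is.na(d$mean_amplitude)],
        duration = function(d)
            d$mean_duration_s[!is.na(d$mean_duration_s)],
        n_bursts = function(d) as.numeric(d$n_bursts))

    ctrl <- summaries[summaries$condition == control, ]
    rows <- list()
    for (mname in names(metrics)) {
        get <- metrics[[mname]]
        x0 <- get(ctrl)
        for (cn in c(control, setdiff(conds, control))) {
            d <- summaries[summaries$condition == cn, ]
            x <- get(d)
            if (!length(x)) {
                rows[[length(rows) + 1L]] <- data.frame(
                    metric = mname, condition = cn, n = 0L,
                    median = NA_real_, median_ratio = NA_real_,
                    statistic = NA_real_, p_value = NA_real_)
                next
            }
            if (cn == control) {
                rows[[length(rows) + 1L]] <- data.frame(
                    metric = mname, condition = cn, n = length(x),
                    median = median(x), median_ratio = 1,
                    statistic = NA_real_, p_value = 1)
            } else {
                tst <- wilcoxonRankSum(x, x0)
                rows[[length(rows) + 1L]] <- data.frame(
                    metric = mname, condition = cn, n = length(x),
                    median = median(x),
                    median_ratio = median(x) / median(x0),
                    statistic = tst$statistic, p_value = tst$p_value)
            }
        }
    }
    out <- do.call(rbind, rows)
    tested <- out$condition != control & !is.na(out$p_value)
    out$p_adj <- NA_real_
    out$p_adj[tested] <- stats::p.adjust(out$p_value[tested], "BH")
    rownames(out) <- NULL
    out
}

# First frame (0-based, on the trace's own axis) whose smoothed value
# exceeds the threshold; NA when never.
onsetFrame <- function(smoothed, threshold) {
    i <- which(!is.na(smoothed) & smoothed > threshold)
    if (length(i)) i[1L] - 1L else NA_integer_
}

#' Render comparison figures and tables
#'
#' Writes, per condition, a trajectory heatmap (one row per nucleus,
#' ordered by transcription onset: the first frame whose smoothed trace
#' exceeds the start threshold), boxplots of total output, amplitude and
#' duration across conditions, a burst-frequency histogram, and TSV copies
#' of every plotted number.
#'
#' @param comparisons data.frame from [compareConditions()].
#' @param traceSets named list of [TraceSet] objects, one per condition.
#' @param summaries the per-nucleus summary table with `condition` column.
#' @param outDir output directory (created if needed).
#' @param config a [BurstCallConfig] (used for smoothing and the onset
#'   threshold; `NA` threshold is resolved from the pooled data).
#' @return Invisibly, the paths written.
#' @export
renderReport <- function(comparisons, traceSets, summaries, outDir,
                         config = BurstCallConfig()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()

    writeTable(comparisons, file.path(outDir, "comparisons.tsv"))
    paths <- c(paths, file.path(outDir, "comparisons.tsv"))

    heatRows <- list()
    for (cn in names(traceSets)) {
        tab <- traceTable(traceSets[[cn]])
        byTrack <- split(tab, tab$track_id)
        sm <- lapply(byTrack, function(d) {
            v <- d$baseline_subtracted
            v[d$missing] <- NA_real_
            smoothSegments(v, config@smoothWindow)
        })
        thr <- if (is.na(config@startThreshold))
            defaultStartThreshold(unlist(sm, use.names = FALSE))
        else config@startThreshold
        onset <- vapply(sm, onsetFrame, integer(1), threshold = thr)
        ord <- order(is.na(onset), onset)
        for (rk in seq_along(ord)) {
            d <- byTrack[[ord[rk]]]
            heatRows[[length(heatRows) + 1L]] <- data.frame(
                condition = cn, row = rk, track_id = d$track_id[1L],
                frame = d$frame, value = d$baseline_subtracted)
        }
    }
    heat <- do.call(rbind, heatRows)
    writeTable(heat, file.path(outDir, "trajectory_heatmap.tsv"))
    paths <- c(paths, file.path(outDir, "trajectory_heatmap.tsv"))

    pHeat <- ggplot2::ggplot(heat, ggplot2::aes(x = frame, y = row, fill = value)) +
        ggplot2::geom_raster() +
        ggplot2::facet_wrap(~condition, scales = "free_y") +
        ggplot2::scale_fill_viridis_c(name = "MS2 (AU)") +
        ggplot2::scale_y_reverse() +
        ggplot2::labs(x = "frame", y = "nucleus (by onset)") +
        ggplot2::theme_minimal()
    f <- file.path(outDir, "trajectories.pdf")
    ggplot2::ggsave(f, pHeat, width = 8, height = 5)
    paths <- c(paths, f)

    long <- do.call(rbind, lapply(
        c(total_output = "total_output", amplitude = "mean_amplitude",
          duration = "mean_duration_s"),
        function(col) data.frame(metric = col,
                                 condition = summaries$condition,
                                 value = summaries[[col]])))
    long <- long[!is.na(long$value), ]
    pBox <- ggplot2::ggplot(long, ggplot2::aes(x = condition, y = value)) +
        ggplot2::geom_boxplot(outlier.size = 0.4) +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(x = NULL, y = NULL) +
        ggplot2::theme_minimal()
    f <- file.path(outDir, "burst_properties.pdf")
    ggplot2::ggsave(f, pBox, width = 8, height = 4)
    paths <- c(paths, f)

    pHist <- ggplot2::ggplot(summaries,
                             ggplot2::aes(x = n_bursts)) +
        ggplot2::geom_histogram(binwidth = 1, boundary = -0.5) +
        ggplot2::facet_wrap(~condition, ncol = 1) +
        ggplot2::labs(x = "bursts per nucleus", y = "nuclei") +
        ggplot2::theme_minimal()
    f <- file.path(outDir, "burst_frequency.pdf")
    ggplot2::ggsave(f, pHist, width = 5, height = 6)
    paths <- c(paths, f)

    invisible(paths)
}
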