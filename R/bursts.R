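#' Centred moving-average smoothing
#'
#' Smooths a trace by averaging within a centred window (default 5 frames);
#' at the edges the window shrinks to the available samples.
#'
#' @param trace numeric vector (no missing values).
#' @param window odd window size in frames, `<= length(trace)`.
#' @return Smoothed numeric vector of the same length.
#' @examples
#' smoothTrace(c(0, 0, 1, 0, 0), 5)
#' @export
smoothTrace <- function(trace, window = 5L) {
    window <- as.integer(window)
    n <- length(trace)
    if (window < 1L || window %% 2L == 0L)
        stopf("'window' must be odd and >= 1")
    if (window > n) stopf("'window' (%d) exceeds trace length (%d)",
                          window, n)
    if (anyNA(trace)) stopf("trace contains missing values; smooth segments")
    h <- (window - 1L) %/% 2L
    cs <- cumsum(c(0, trace))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Smooth a trace that may contain NA runs, per contiguous segment.
# Segments shorter than the window are left unsmoothed (identity).
smoothSegments <- function(trace, window) {
    out <- rep(NA_real_, length(trace))
    ok <- !is.na(trace)
    if (!any(ok)) return(out)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
        seg <- trace[starts[i]:ends[i]]
        out[starts[i]:ends[i]] <-
            if (length(seg) >= window) smoothTrace(seg, window) else seg
    }
    out
}

# State machine on one NA-free smoothed segment. Frames 1-based internal;
# returns 0-based inclusive intervals relative to segment start.
detectBurstsSegment <- function(s, config) {
    thr <- config@startThreshold
    frac <- config@endFraction
    n <- length(s)
    cand <- list()
    i <- 1L
    while (i <= n) {
        if (s[i] > thr) {
            start <- i
            peak <- s[i]
            j <- i + 1L
            end <- n
            while (j <= n) {
                peak <- max(peak, s[j])
                if (s[j] < frac * peak) {       # first sub-fraction frame is
                    end <- j - 1L               # the exclusive boundary
                    break
                }
                j <- j + 1L
            }
            cand[[length(cand) + 1L]] <-
                list(start = start, end = end, peak = peak)
            i <- max(j, end + 1L) + 1L
        } else {
            i <- i + 1L
        }
    }
    out <- list()
    for (b in cand) {
        dur <- b$end - b$start + 1L
        if (dur < config@minDuration) next      # false positive
        L <- min(config@decreasingStartLen, dur)
        if (L >= 2L) {
            open <- s[b$start:(b$start + L - 1L)]
            if (all(diff(open) < 0)) next       # decreasing onset artefact
        }
        st <- b$start + config@shift
        en <- min(b$end + config@shift, n)
        if (st > n) next
        st <- min(st, n)
        if (en < st) next
        prev <- if (length(out)) out[[length(out)]] else NULL
        if (!is.null(prev) && st <= prev$end) next  # clamping collision
        out[[length(out) + 1L]] <-
            list(start = st - 1L, end = en - 1L, peak = b$peak)
    }
    out
}

#' Detect transcriptional bursts on a smoothed, baseline-zeroed trace
#'
#' Rule-based caller: a burst opens at the first frame whose smoothed value
#' exceeds `startThreshold`; while open, the running (local) peak is
#' tracked, and the burst terminates at the first frame whose value drops
#' below `endFraction` of that peak (that frame is the exclusive boundary).
#' Candidates shorter than `minDuration` frames are discarded as detection
#' noise, as are candidates whose smoothed values strictly decrease over
#' the opening `decreasingStartLen` frames (a burst already decaying when
#' observation starts). Surviving intervals are translated `shift` frames
#' later (clamped to the trace end). Missing (`NA`) stretches split the
#' trace into independently processed segments.
#'
#' @param smoothed numeric vector from [smoothTrace()] (NA = missing frame).
#' @param config a [BurstCallConfig]; `startThreshold` must be set.
#' @return data.frame with columns `start_frame`, `end_frame` (0-based,
#'   inclusive, post-shift), `duration_frames`, `local_peak`, `amplitude`
#'   (max of the smoothed trace within the called interval); zero rows when
#'   no burst is found.
#' @export
detectBursts <- function(smoothed, config) {
    stopifnot(is(config, "BurstCallConfig"))
    validObject(config)
    if (is.na(config@startThreshold))
        stopf("'startThreshold' is unset; see defaultStartThreshold()")
    empty <- data.frame(start_frame = integer(), end_frame = integer(),
                        duration_frames = integer(), local_peak = numeric(),
                        amplitude = numeric())
    n <- length(smoothed)
    if (!n) return(empty)
    ok <- !is.na(smoothed)
    if (!any(ok)) return(empty)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    rows <- list()
    for (i in which(r$values)) {
        seg <- smoothed[starts[i]:ends[i]]
        for (b in detectBurstsSegment(seg, config)) {
            st <- b$start + starts[i] - 1L     # back to 0-based trace frame
            en <- b$end + starts[i] - 1L
            rows[[length(rows) + 1L]] <- data.frame(
                start_frame = st, end_frame = en,
                duration_frames = en - st + 1L,
                local_peak = b$peak,
                amplitude = max(smoothed[(st + 1L):(en + 1L)]))
        }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out[order(out$start_frame), ]
}

#' Data-derived default burst start threshold
#'
#' The caller needs one threshold per experiment set (the same value for
#' every condition of a set). When none is supplied it is derived from the
#' control condition as 10% of the pooled 99th percentile of the smoothed,
#' baseline-zeroed traces — tying the gate to the signal scale of the
#' experiment.
#'
#' @param smoothedValues numeric vector: pooled smoothed trace values of
#'   the control condition (NAs ignored).
#' @return numeric(1) threshold.
#' @export
defaultStartThreshold <- function(smoothedValues) {
    v <- smoothedValues[!is.na(smoothedValues)]
    if (!length(v)) stopf("no values to derive a start threshold from")
    0.10 * quantile(v, 0.99, names = FALSE)
}

#' Per-nucleus burst properties
#'
#' Summarizes one trajectory: burst count, per-burst amplitude (peak of the
#' smoothed trace within the called interval) and duration, their
#' per-nucleus means, and the total transcriptional output (area under the
#' raw trajectory over the analysis window, i.e. the plain sum of the raw
#' trace in intensity x frames).
#'
#' @param raw numeric raw trace (baseline-zeroed; NA = missing frame).
#' @param smoothed matching smoothed trace.
#' @param bursts data.frame from [detectBursts()].
#' @param frameInterval seconds per frame (for durations in seconds).
#' @return one-row data.frame: `n_bursts`, `mean_amplitude`,
#'   `mean_duration_frames`, `mean_duration_s`, `total_output`. Amplitude
#'   and duration are `NA` when no burst was called.
#' @export
burstProperties <- function(raw, smoothed, bursts, frameInterval = 1) {
    total <- sum(raw, na.rm = TRUE)
    if (!nrow(bursts))
        return(data.frame(n_bursts = 0L, mean_amplitude = NA_real_,
                          mean_duration_frames = NA_real_,
                          mean_duration_s = NA_real_,
                          total_output = total))
    data.frame(n_bursts = nrow(bursts),
               mean_amplitude = mean(bursts$amplitude),
               mean_duration_frames = mean(bursts$duration_frames),
               mean_duration_s = mean(bursts$duration_frames) *
                   frameInterval,
               total_output = total)
}

#' Call bursts and summarize properties for every track of a TraceSet
#'
#' Smooths each baseline-zeroed trace, resolves the start threshold
#' (data-derived default when `config@startThreshold` is `NA`), runs
#' [detectBursts()], and assembles per-burst and per-nucleus tables.
#'
#' @param traceSet a [TraceSet].
#' @param config a [BurstCallConfig].
#' @return list: `bursts` (per burst: `track_id`, `start_frame`,
#'   `end_frame`, `duration_frames`, `duration_s`, `local_peak`,
#'   `amplitude`), `summary` (per track, see [burstProperties()]),
#'   `startThreshold` (the resolved value).
#' @export
summarizeBursts <- function(traceSet, config = BurstCallConfig()) {
    stopifnot(is(traceSet, "TraceSet"))
    tab <- traceTable(traceSet)
    dt <- frameInterval(traceSet)
    byTrack <- split(tab, tab$track_id)
    smoothed <- lapply(byTrack, function(d) {
        v <- d$baseline_subtracted
        v[d$missing] <- NA_real_
        smoothSegments(v, config@smoothWindow)
    })
    if (is.na(config@startThreshold)) {
        thr <- defaultStartThreshold(unlist(smoothed, use.names = FALSE))
        config@startThreshold <- thr
    }
    burstsL <- vector("list", length(byTrack))
    sumL <- vector("list", length(byTrack))
    for (i in seq_along(byTrack)) {
        d <- byTrack[[i]]
        raw <- d$baseline_subtracted
        raw[d$missing] <- NA_real_
        b <- detectBursts(smoothed[[i]], config)
        props <- burstProperties(raw, smoothed[[i]], b, dt)
        id <- d$track_id[1L]
        if (nrow(b)) {
            # report frames on the track's own (absolute) frame axis
            b$start_frame <- b$start_frame + d$frame[1L]
            b$end_frame <- b$end_frame + d$frame[1L]
            burstsL[[i]] <- cbind(track_id = id, b,
                                  duration_s = b$duration_frames * dt)
        }
        sumL[[i]] <- cbind(track_id = id, props)
    }
    bursts <- do.call(rbind, burstsL[!vapply(burstsL, is.null, logical(1))])
    if (is.null(bursts))
        bursts <- data.frame(track_id = integer(), start_frame = integer(),
                             end_frame = integer(),
                             duration_frames = integer(),
                             local_peak = numeric(), amplitude = numeric(),
                             duration_s = numeric())
    summary <- do.call(rbind, sumL)
    rownames(bursts) <- rownames(summary) <- NULL
    list(bursts = bursts, summary = summary,
         startThreshold = config@startThreshold)
}
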