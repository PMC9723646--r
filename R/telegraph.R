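#' Simulate a two-state (telegraph) promoter trace
#'
#' Runs an exact continuous-time (Gillespie) simulation of the two-state
#' promoter: the promoter alternates between OFF and ON with exponential
#' waiting times (`kOn`, `kOff`); while ON, transcripts initiate as a
#' Poisson process at `loadingRate`. Each initiated transcript contributes
#' one unit of signal for `dwellTime` seconds (a boxcar), so the signal at
#' frame time `t` is the number of initiations in `(t - dwellTime, t]`.
#' The continuous-time realization is sampled at frame boundaries
#' `0, dt, 2*dt, ...`.
#'
#' @param params a [TelegraphParams] object.
#' @param frameCount number of frames to sample (>= 1).
#' @param frameInterval seconds per frame.
#' @param seed integer RNG seed; defaults to the seed stored in `params`.
#' @param initialState `"off"` (default), `"on"`, or `"stationary"` (drawn
#'   with probability `kOn / (kOn + kOff)` of starting ON).
#'
#' @return A list with elements
#'   \item{trace}{numeric vector of length `frameCount`: transcript count
#'     within the trailing dwell window at each frame time.}
#'   \item{onIntervals}{data.frame (`start_frame`, `end_frame`, inclusive,
#'     0-based) of maximal runs of frames at which the promoter was ON.}
#'   \item{onFraction}{fraction of continuous simulated time spent ON.}
#'   \item{initiationTimes}{sorted initiation times (s).}
#'
#' @examples
#' p <- TelegraphParams(kOn = 0.01, kOff = 0.02, loadingRate = 0.3,
#'                      dwellTime = 120, seed = 7)
#' sim <- simulateTelegraph(p, frameCount = 100, frameInterval = 16.8)
#' head(sim$trace)
#' @export
simulateTelegraph <- function(params, frameCount, frameInterval,
                              seed = params@seed,
                              initialState = c("off", "on", "stationary")) {
    stopifnot(is(params, "TelegraphParams"))
    validObject(params)
    initialState <- match.arg(initialState)
    frameCount <- as.integer(frameCount)
    if (frameCount < 1L) stopf("'frameCount' must be >= 1")
    if (frameInterval <= 0) stopf("'frameInterval' must be > 0")

    totalTime <- frameCount * frameInterval
    frameTimes <- (seq_len(frameCount) - 1L) * frameInterval

    withSeed(seed, {
        state <- switch(initialState,
            off = FALSE,
            on = TRUE,
            stationary = runif(1) < params@kOn / (params@kOn + params@kOff))

        t <- 0
        onStarts <- numeric()
        onEnds <- numeric()
        initTimes <- numeric()
        while (t < totalTime) {
            if (state) {
                dt <- rexp(1L, params@kOff)
                segEnd <- min(t + dt, totalTime)
                onStarts <- c(onStarts, t)
                onEnds <- c(onEnds, segEnd)
                n <- rpois(1L, params@loadingRate * (segEnd - t))
                if (n > 0L)
                    initTimes <- c(initTimes, runif(n, t, segEnd))
                t <- t + dt
                state <- FALSE
            } else {
                if (params@kOn == 0) break     # never-ON control
                t <- t + rexp(1L, params@kOn)
                state <- TRUE
            }
        }
        initTimes <- sort(initTimes)

        trace <- findInterval(frameTimes, initTimes) -
            findInterval(frameTimes - params@dwellTime, initTimes)

        onAtFrame <- vapply(frameTimes, function(ft)
            any(onStarts <= ft & ft < onEnds), logical(1))

        list(trace = as.numeric(trace),
             onIntervals = trueRuns(onAtFrame),
             onFraction = if (totalTime > 0) sum(onEnds - onStarts) / totalTime
                          else 0,
             initiationTimes = initTimes)
    })
}

#' Simulate measured traces for a whole condition (no rendering)
#'
#' Generates one telegraph realization per nucleus, converts transcript
#' counts to intensity units, adds Gaussian measurement noise (emulating
#' spot-quantification error), and baseline-zeroes each trajectory — i.e.
#' produces a [TraceSet] shaped exactly like the output of
#' [extractTraces()], but orders of magnitude faster than rendering and
#' re-analysing a movie. Intended for burst-caller benchmarking and
#' between-condition statistics at scale.
#'
#' @param params a [TelegraphParams] describing the condition.
#' @param nNuclei number of nuclei (traces).
#' @param frameCount,frameInterval sampling grid.
#' @param unitIntensity intensity units per nascent transcript.
#' @param noiseSd standard deviation of additive measurement noise
#'   (intensity units).
#' @param seed master seed; per-nucleus seeds derived from it.
#' @return list: `traces` (a [TraceSet], track ids `1..nNuclei`), `truth`
#'   (data.frame `label`, `start_frame`, `end_frame` of promoter-ON runs),
#'   `trueTotals` (per-nucleus summed true intensity).
#' @export
simulateTraceSet <- function(params, nNuclei, frameCount, frameInterval,
                             unitIntensity = 40, noiseSd = 0, seed = 1L) {
    rows <- vector("list", nNuclei)
    onIv <- vector("list", nNuclei)
    totals <- numeric(nNuclei)
    for (i in seq_len(nNuclei)) {
        sim <- simulateTelegraph(params, frameCount, frameInterval,
                                 seed = childSeed(seed, i))
        v <- sim$trace * unitIntensity
        totals[i] <- sum(v)
        if (noiseSd > 0)
            v <- withSeed(childSeed(seed, nNuclei + i),
                          v + rnorm(frameCount, 0, noiseSd))
        v <- v - min(v)
        rows[[i]] <- data.frame(track_id = i,
                                frame = seq_len(frameCount) - 1L,
                                raw = v, baseline_subtracted = v,
                                fit_ok = TRUE, missing = FALSE)
        if (nrow(sim$onIntervals))
            onIv[[i]] <- cbind(label = i, sim$onIntervals)
    }
    onIv <- onIv[!vapply(onIv, is.null, logical(1))]
    list(traces = new("TraceSet", traces = do.call(rbind, rows),
                      fits = data.frame(), frameInterval = frameInterval),
         truth = if (length(onIv)) do.call(rbind, onIv)
                 else data.frame(label = integer(), start_frame = integer(),
                                 end_frame = integer()),
         trueTotals = totals)
}
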