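#' @import methods
#' @importFrom stats median quantile rnorm rpois rexp runif sd setNames
#' @importFrom utils head tail write.table read.delim combn
NULL

#' Two-state (telegraph) promoter kinetics
#'
#' Parameters of the two-state stochastic promoter model used by the
#' synthetic-movie generator: the promoter switches ON with rate `kOn` and
#' OFF with rate `kOff`; while ON it initiates transcripts at `loadingRate`,
#' and each nascent transcript contributes one unit of signal for
#' `dwellTime` seconds (the residence time of the transcript at the locus).
#'
#' @slot kOn numeric(1), ON-switching rate in 1/s. `kOn = 0` is permitted
#'   and yields a never-active control.
#' @slot kOff numeric(1), OFF-switching rate in 1/s; strictly positive.
#' @slot loadingRate numeric(1), initiation events per second while ON;
#'   strictly positive.
#' @slot dwellTime numeric(1), signal residence time of one transcript in
#'   seconds; strictly positive.
#' @slot seed integer(1), RNG seed used when the parameters are simulated
#'   on their own.
#'
#' @seealso [simulateTelegraph()]
#' @export
setClass("TelegraphParams",
    representation(
        kOn = "numeric",
        kOff = "numeric",
        loadingRate = "numeric",
        dwellTime = "numeric",
        seed = "integer"
    ),
    prototype(
        kOn = 0.008, kOff = 0.012, loadingRate = 0.2, dwellTime = 150,
        seed = 1L
    )
)

setValidity("TelegraphParams", function(object) {
    msg <- character()
    num1 <- function(x) length(x) == 1L && is.finite(x)
    if (!num1(object@kOn) || object@kOn < 0)
        msg <- c(msg, "'kOn' must be a single finite value >= 0")
    if (!num1(object@kOff) || object@kOff <= 0)
        msg <- c(msg, "'kOff' must be a single finite value > 0")
    if (!num1(object@loadingRate) || object@loadingRate <= 0)
        msg <- c(msg, "'loadingRate' must be a single finite value > 0")
    if (!num1(object@dwellTime) || object@dwellTime <= 0)
        msg <- c(msg, "'dwellTime' must be a single finite value > 0")
    if (length(msg)) msg else TRUE
})

#' @rdname TelegraphParams-class
#' @param kOn,kOff,loadingRate,dwellTime,seed see slot documentation.
#' @return A `TelegraphParams` object.
#' @examples
#' TelegraphParams(kOn = 0.01, kOff = 0.02, loadingRate = 0.25, dwellTime = 120)
#' @export
TelegraphParams <- function(kOn = 0.008, kOff = 0.012, loadingRate = 0.2,
                            dwellTime = 150, seed = 1L) {
    new("TelegraphParams", kOn = kOn, kOff = kOff, loadingRate = loadingRate,
        dwellTime = dwellTime, seed = as.integer(seed))
}

#' Scene description for the synthetic movie generator
#'
#' Describes one synthetic two-channel movie: field geometry, nucleus
#' appearance, stage drift, the point-spread function of the transcription
#' spot, the detector noise model, and the telegraph kinetics of each
#' condition.
#'
#' @slot nNuclei integer(1), number of nuclei in the field.
#' @slot frameCount integer(1), number of time frames.
#' @slot frameInterval numeric(1), seconds per frame.
#' @slot imageShape integer(3), image dimensions as (z, rows, cols).
#' @slot nucleusRadius numeric(1), nucleus radius in pixels.
#' @slot driftSigma numeric(1), standard deviation of the per-frame
#'   field-wide drift step, pixels/frame.
#' @slot psfSigma numeric(2), Gaussian spot spreads (sigma_y, sigma_x) px.
#' @slot backgroundLevel numeric(1), additive background of the spot
#'   channel, intensity units.
#' @slot nucleusIntensity numeric(1), plateau intensity of a rendered
#'   nucleus in the histone channel.
#' @slot unitIntensity numeric(1), integrated spot intensity contributed by
#'   a single nascent transcript.
#' @slot spotOffset numeric(2), fixed (row, col) offset of the transcription
#'   spot from the nucleus centroid, pixels.
#' @slot noisePoissonGain numeric(1), gain of the Poisson (shot) noise;
#'   0 disables shot noise.
#' @slot noiseReadSd numeric(1), standard deviation of additive Gaussian
#'   read noise; 0 disables it.
#' @slot kinetics `TelegraphParams`, promoter kinetics of this condition.
#' @slot seed integer(1), master RNG seed.
#'
#' @seealso [renderMovie()], [makeFixture()], [demoScene()]
#' @export
setClass("SceneConfig",
    representation(
        nNuclei = "integer",
        frameCount = "integer",
        frameInterval = "numeric",
        imageShape = "integer",
        nucleusRadius = "numeric",
        driftSigma = "numeric",
        psfSigma = "numeric",
        backgroundLevel = "numeric",
        nucleusIntensity = "numeric",
        unitIntensity = "numeric",
        spotOffset = "numeric",
        noisePoissonGain = "numeric",
        noiseReadSd = "numeric",
        kinetics = "TelegraphParams",
        seed = "integer"
    )
)

setValidity("SceneConfig", function(object) {
    msg <- character()
    if (object@nNuclei < 0L) msg <- c(msg, "'nNuclei' must be >= 0")
    if (object@frameCount < 1L) msg <- c(msg, "'frameCount' must be >= 1")
    if (object@frameInterval <= 0) msg <- c(msg, "'frameInterval' must be > 0")
    if (length(object@imageShape) != 3L || any(object@imageShape < 1L))
        msg <- c(msg, "'imageShape' must be positive (z, rows, cols)")
    if (object@nucleusRadius <= 0) msg <- c(msg, "'nucleusRadius' must be > 0")
    if (object@driftSigma < 0) msg <- c(msg, "'driftSigma' must be >= 0")
    if (length(object@psfSigma) != 2L || any(object@psfSigma <= 0))
        msg <- c(msg, "'psfSigma' must be two positive values (sigma_y, sigma_x)")
    if (object@backgroundLevel < 0) msg <- c(msg, "'backgroundLevel' must be >= 0")
    if (object@noisePoissonGain < 0) msg <- c(msg, "'noisePoissonGain' must be >= 0")
    if (object@noiseReadSd < 0) msg <- c(msg, "'noiseReadSd' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname SceneConfig-class
#' @param nNuclei,frameCount,frameInterval,imageShape,nucleusRadius,driftSigma
#'   see slot documentation.
#' @param psfSigma,backgroundLevel,nucleusIntensity,unitIntensity,spotOffset
#'   see slot documentation.
#' @param noisePoissonGain,noiseReadSd,kinetics,seed see slot documentation.
#' @return A `SceneConfig` object.
#' @export
SceneConfig <- function(nNuclei = 50L, frameCount = 200L,
                        frameInterval = 16.8,
                        imageShape = c(3L, 300L, 430L),
                        nucleusRadius = 8, driftSigma = 0.5,
                        psfSigma = c(2, 2), backgroundLevel = 100,
                        nucleusIntensity = 600, unitIntensity = 40,
                        spotOffset = c(1.7, 2.3),
                        noisePoissonGain = 1, noiseReadSd = 3,
                        kinetics = TelegraphParams(), seed = 1L) {
    new("SceneConfig",
        nNuclei = as.integer(nNuclei), frameCount = as.integer(frameCount),
        frameInterval = frameInterval, imageShape = as.integer(imageShape),
        nucleusRadius = nucleusRadius, driftSigma = driftSigma,
        psfSigma = psfSigma, backgroundLevel = backgroundLevel,
        nucleusIntensity = nucleusIntensity, unitIntensity = unitIntensity,
        spotOffset = spotOffset, noisePoissonGain = noisePoissonGain,
        noiseReadSd = noiseReadSd, kinetics = kinetics,
        seed = as.integer(seed))
}

#' Two-channel 4-D movie stack
#'
#' Container for an aligned pair of 4-D intensity arrays: the transcription
#' (MS2/MCP) channel and the nuclei (histone marker) channel, both indexed
#' as (frame, z, row, col), together with physical acquisition metadata.
#'
#' @slot ms2 4-D numeric array, transcription-spot channel.
#' @slot nuclei 4-D numeric array, nuclei channel; same dimensions as `ms2`.
#' @slot frameInterval numeric(1), seconds per frame.
#' @slot pixelSize numeric(1), micrometres per pixel.
#' @slot zStep numeric(1), micrometres between z-sections.
#'
#' @seealso [readMovie()], [writeMovie()], [segmentMovie()]
#' @export
setClass("MovieStack",
    representation(
        ms2 = "array",
        nuclei = "array",
        frameInterval = "numeric",
        pixelSize = "numeric",
        zStep = "numeric"
    )
)

setValidity("MovieStack", function(object) {
    msg <- character()
    if (length(dim(object@ms2)) != 4L)
        msg <- c(msg, "'ms2' must be a 4-D array (frame, z, row, col)")
    if (!identical(dim(object@ms2), dim(object@nuclei)))
        msg <- c(msg, "channels must share dimensions")
    if (any(object@ms2 < 0) || any(object@nuclei < 0))
        msg <- c(msg, "intensities must be >= 0")
    if (object@frameInterval <= 0)
        msg <- c(msg, "'frameInterval' must be > 0")
    if (length(msg)) msg else TRUE
})

#' @rdname MovieStack-class
#' @param ms2,nuclei,frameInterval,pixelSize,zStep see slot documentation.
#' @return A `MovieStack` object.
#' @export
MovieStack <- function(ms2, nuclei, frameInterval = 16.8, pixelSize = 0.2,
                       zStep = 0.5) {
    new("MovieStack", ms2 = ms2, nuclei = nuclei,
        frameInterval = frameInterval, pixelSize = pixelSize, zStep = zStep)
}

#' Simulator ground truth
#'
#' Everything the synthetic movie generator knows about what it rendered:
#' true nucleus centroids per frame, true intensity traces, true promoter-ON
#' intervals, and true subpixel spot positions.
#'
#' @slot centroids data.frame with columns `frame`, `label`, `row`, `col`
#'   (0-based frame index; subpixel 0-based pixel-centre coordinates).
#' @slot traces data.frame with columns `label`, `frame`, `value`
#'   (rendered-intensity units; the background-subtracted spot integral).
#' @slot onIntervals data.frame with columns `label`, `start_frame`,
#'   `end_frame` (inclusive frame indices of promoter-ON runs).
#' @slot spotPositions data.frame with columns `frame`, `label`, `row`, `col`.
#'
#' @export
setClass("GroundTruth",
    representation(
        centroids = "data.frame",
        traces = "data.frame",
        onIntervals = "data.frame",
        spotPositions = "data.frame"
    )
)

setValidity("GroundTruth", function(object) {
    msg <- character()
    oi <- object@onIntervals
    if (nrow(oi) && any(oi$end_frame < oi$start_frame))
        msg <- c(msg, "ON intervals must satisfy end_frame >= start_frame")
    if (nrow(oi)) {
        bad <- vapply(split(oi, oi$label), function(d) {
            d <- d[order(d$start_frame), ]
            nrow(d) > 1L && any(d$start_frame[-1L] <= d$end_frame[-nrow(d)])
        }, logical(1))
        if (any(bad)) msg <- c(msg, "ON intervals of one nucleus must not overlap")
    }
    if (length(msg)) msg else TRUE
})

#' Segmentation result for a whole movie
#'
#' Per-frame nucleus label images, Voronoi measurement territories, a region
#' table, and a per-frame QC record.
#'
#' @slot labels list of integer matrices, one per frame; 0 = background.
#' @slot territories list of integer matrices; every pixel assigned to its
#'   nearest nucleus centroid (the measurement territory of that nucleus).
#' @slot regions data.frame: `frame`, `label`, `centroid_row`,
#'   `centroid_col`, `area`.
#' @slot qc data.frame: `frame`, `n_components`, `threshold`, `degraded`.
#' @slot cropBox integer(4): (row0, col0, rows, cols), 0-based half-open
#'   crop applied to each projected frame before segmentation.
#'
#' @seealso [segmentMovie()], [trackMovie()]
#' @export
setClass("SegmentedMovie",
    representation(
        labels = "list",
        territories = "list",
        regions = "data.frame",
        qc = "data.frame",
        cropBox = "integer"
    )
)

setValidity("SegmentedMovie", function(object) {
    msg <- character()
    if (length(object@labels) != length(object@territories))
        msg <- c(msg, "'labels' and 'territories' must have one entry per frame")
    if (nrow(object@regions) && any(object@regions$label <= 0L))
        msg <- c(msg, "region labels must be positive")
    if (length(msg)) msg else TRUE
})

#' Per-track transcription traces
#'
#' Raw spot-integral traces per tracked nucleus, together with the
#' baseline-subtracted version (per-track minimum over valid frames set to
#' zero). Frames where the nucleus was not detected are recorded as missing
#' (`NA`), distinct from fit failures which contribute an integral of 0.
#'
#' @slot traces data.frame with columns `track_id`, `frame`, `raw`,
#'   `baseline_subtracted`, `fit_ok`, `missing`.
#' @slot fits data.frame of per-frame Gaussian fit records (may be empty):
#'   `track_id`, `frame`, `z_index`, `x0`, `y0`, `alpha`, `i0`, `sigma_x`,
#'   `sigma_y`, `integral`, `fit_ok`.
#' @slot frameInterval numeric(1), seconds per frame.
#'
#' @seealso [extractTraces()], [detectBursts()]
#' @export
setClass("TraceSet",
    representation(traces = "data.frame", fits = "data.frame",
                   frameInterval = "numeric"),
    prototype(fits = data.frame())
)

setValidity("TraceSet", function(object) {
    need <- c("track_id", "frame", "raw", "baseline_subtracted", "fit_ok",
              "missing")
    if (!all(need %in% names(object@traces)))
        return(paste("trace table must have columns:",
                     paste(need, collapse = ", ")))
    tr <- object@traces[!object@traces$missing, ]
    if (nrow(tr)) {
        mins <- tapply(tr$baseline_subtracted, tr$track_id, min)
        if (any(abs(mins) > 1e-8))
            return("baseline-subtracted traces must have minimum 0")
    }
    TRUE
})

#' Burst-calling configuration
#'
#' Tuning parameters of the rule-based burst caller. Defaults follow the
#' standard recipe: 5-frame moving-average smoothing, burst termination when
#' the smoothed signal drops below 55% of the running (local) peak, a
#' minimum duration of 5 frames, rejection of candidate bursts that open
#' with a strictly decreasing stretch, and a +2-frame shift of the called
#' interval.
#'
#' @slot smoothWindow integer(1), odd moving-average window (frames).
#' @slot startThreshold numeric(1), smoothed-intensity threshold that opens
#'   a burst. `NA` means: derive it from the data as 10% of the pooled 99th
#'   percentile of the smoothed control traces (see [defaultStartThreshold()]).
#' @slot endFraction numeric(1) in (0, 1), fraction of the running peak
#'   below which a burst terminates.
#' @slot minDuration integer(1), minimum burst duration in frames.
#' @slot shift integer(1), frames by which called intervals are translated.
#' @slot decreasingStartLen integer(1), length of the opening window tested
#'   for a strictly decreasing start.
#'
#' @seealso [detectBursts()], [burstProperties()]
#' @export
setClass("BurstCallConfig",
    representation(
        smoothWindow = "integer",
        startThreshold = "numeric",
        endFraction = "numeric",
        minDuration = "integer",
        shift = "integer",
        decreasingStartLen = "integer"
    ),
    prototype(
        smoothWindow = 5L, startThreshold = NA_real_, endFraction = 0.55,
        minDuration = 5L, shift = 2L, decreasingStartLen = 5L
    )
)

setValidity("BurstCallConfig", function(object) {
    msg <- character()
    if (object@smoothWindow < 1L || object@smoothWindow %% 2L == 0L)
        msg <- c(msg, "'smoothWindow' must be odd and >= 1")
    if (!is.na(object@startThreshold) && object@startThreshold < 0)
        msg <- c(msg, "'startThreshold' must be >= 0")
    if (object@endFraction <= 0 || object@endFraction >= 1)
        msg <- c(msg, "'endFraction' must be in (0, 1)")
    if (object@minDuration < 1L) msg <- c(msg, "'minDuration' must be >= 1")
    if (object@shift < 0L) msg <- c(msg, "'shift' must be >= 0")
    if (object@decreasingStartLen < 1L)
        msg <- c(msg, "'decreasingStartLen' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname BurstCallConfig-class
#' @param smoothWindow,startThreshold,endFraction,minDuration,shift,decreasingStartLen
#'   see slot documentation.
#' @return A `BurstCallConfig` object.
#' @examples
#' BurstCallConfig(startThreshold = 25)
#' @export
BurstCallConfig <- function(smoothWindow = 5L, startThreshold = NA_real_,
                            endFraction = 0.55, minDuration = 5L, shift = 2L,
                            decreasingStartLen = smoothWindow) {
    new("BurstCallConfig", smoothWindow = as.integer(smoothWindow),
        startThreshold = as.numeric(startThreshold),
        endFraction = endFraction, minDuration = as.integer(minDuration),
        shift = as.integer(shift),
        decreasingStartLen = as.integer(decreasingStartLen))
}
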