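#' @rdname MovieStack-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("ms2Channel", function(x) standardGeneric("ms2Channel"))

#' @rdname MovieStack-class
#' @export
setGeneric("nucleiChannel", function(x) standardGeneric("nucleiChannel"))

#' @rdname MovieStack-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname MovieStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname SegmentedMovie-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("labelImages", function(x) standardGeneric("labelImages"))

#' @rdname SegmentedMovie-class
#' @export
setGeneric("territoryImages", function(x) standardGeneric("territoryImages"))

#' @rdname SegmentedMovie-class
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname SegmentedMovie-class
#' @export
setGeneric("qcTable", function(x) standardGeneric("qcTable"))

#' @rdname SegmentedMovie-class
#' @export
setGeneric("cropBox", function(x) standardGeneric("cropBox"))

#' @rdname TraceSet-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("traceTable", function(x) standardGeneric("traceTable"))

#' @rdname GroundTruth-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("trueCentroids", function(x) standardGeneric("trueCentroids"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueTraces", function(x) standardGeneric("trueTraces"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueOnIntervals", function(x) standardGeneric("trueOnIntervals"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueSpotPositions",
           function(x) standardGeneric("trueSpotPositions"))

#' @rdname MovieStack-class
#' @export
setMethod("ms2Channel", "MovieStack", function(x) x@ms2)

#' @rdname MovieStack-class
#' @export
setMethod("nucleiChannel", "MovieStack", function(x) x@nuclei)

#' @rdname MovieStack-class
#' @export
setMethod("frameInterval", "MovieStack", function(x) x@frameInterval)

#' @rdname MovieStack-class
#' @export
setMethod("frameInterval", "TraceSet", function(x) x@frameInterval)

#' @rdname MovieStack-class
#' @export
setMethod("nFrames", "MovieStack", function(x) dim(x@ms2)[1L])

#' @rdname SegmentedMovie-class
#' @export
setMethod("nFrames", "SegmentedMovie", function(x) length(x@labels))

#' @rdname SegmentedMovie-class
#' @export
setMethod("labelImages", "SegmentedMovie", function(x) x@labels)

#' @rdname SegmentedMovie-class
#' @export
setMethod("territoryImages", "SegmentedMovie", function(x) x@territories)

#' @rdname SegmentedMovie-class
#' @export
setMethod("regionTable", "SegmentedMovie", function(x) x@regions)

#' @rdname SegmentedMovie-class
#' @export
setMethod("qcTable", "SegmentedMovie", function(x) x@qc)

#' @rdname SegmentedMovie-class
#' @export
setMethod("cropBox", "SegmentedMovie", function(x) x@cropBox)

#' @rdname TraceSet-class
#' @export
setGeneric("spotFits", function(x) standardGeneric("spotFits"))

#' @rdname TraceSet-class
#' @export
setMethod("traceTable", "TraceSet", function(x) x@traces)

#' @rdname TraceSet-class
#' @export
setMethod("spotFits", "TraceSet", function(x) x@fits)

#' @rdname GroundTruth-class
#' @export
setMethod("trueCentroids", "GroundTruth", function(x) x@centroids)

#' @rdname GroundTruth-class
#' @export
setMethod("trueTraces", "GroundTruth", function(x) x@traces)

#' @rdname GroundTruth-class
#' @export
setMethod("trueOnIntervals", "GroundTruth", function(x) x@onIntervals)

#' @rdname GroundTruth-class
#' @export
setMethod("trueSpotPositions", "GroundTruth", function(x) x@spotPositions)

setMethod("show", "TelegraphParams", function(object) {
    cat("TelegraphParams: k_on =", object@kOn, "/s, k_off =", object@kOff,
        "/s, loading =", object@loadingRate, "/s, dwell =", object@dwellTime,
        "s\n")
})

setMethod("show", "SceneConfig", function(object) {
    cat("SceneConfig:", object@nNuclei, "nuclei,", object@frameCount,
        "frames @", object@frameInterval, "s, image (z,rows,cols) =",
        paste(object@imageShape, collapse = "x"), "\n")
    cat("  nucleus radius", object@nucleusRadius, "px, drift sigma",
        object@driftSigma, "px/frame, psf sigma",
        paste(object@psfSigma, collapse = "/"), "px\n")
    cat("  background", object@backgroundLevel, ", poisson gain",
        object@noisePoissonGain, ", read sd", object@noiseReadSd, "\n")
    cat("  kinetics: ")
    show(object@kinetics)
})

setMethod("show", "MovieStack", function(object) {
    d <- dim(object@ms2)
    cat("MovieStack:", d[1L], "frames,", d[2L], "z,", d[3L], "x", d[4L],
        "px;", object@frameInterval, "s/frame\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(unique(object@centroids$label)), "nuclei,",
        length(unique(object@centroids$frame)), "frames,",
        nrow(object@onIntervals), "promoter-ON intervals\n")
})

setMethod("show", "SegmentedMovie", function(object) {
    cat("SegmentedMovie:", length(object@labels), "frames,",
        nrow(object@regions), "region records,",
        sum(object@qc$degraded), "degraded frames\n")
})

setMethod("show", "TraceSet", function(object) {
    cat("TraceSet:", length(unique(object@traces$track_id)), "tracks,",
        nrow(object@traces), "frame records;", object@frameInterval,
        "s/frame\n")
})

setMethod("show", "BurstCallConfig", function(object) {
    cat("BurstCallConfig: smooth", object@smoothWindow, "frames, threshold",
        if (is.na(object@startThreshold)) "(auto)" else object@startThreshold,
        ", end at", object@endFraction, "x running peak, min duration",
        object@minDuration, "frames, shift +", object@shift, "\n")
})
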