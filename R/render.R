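#' @include AllClasses.R
NULL

# Grid-with-jitter placement guaranteeing surface separation >= 4 px.
placeNuclei <- function(n, rows, cols, radius) {
    if (n == 0L)
        return(data.frame(row = numeric(), col = numeric()))
    margin <- radius + 5
    minSpacing <- 2 * radius + 4
    usableR <- rows - 2 * margin
    usableC <- cols - 2 * margin
    if (usableR < 0 || usableC < 0)
        stopf("image %dx%d too small for nuclei of radius %g", rows, cols,
              radius)
    # largest grid spacing that still yields >= n cells
    s <- sqrt(max(usableR, 1) * max(usableC, 1) / n) * 1.5
    repeat {
        gr <- floor(usableR / s) + 1L
        gc <- floor(usableC / s) + 1L
        if (gr * gc >= n) break
        s <- s * 0.97
        if (s < minSpacing)
            stopf("cannot place %d non-overlapping nuclei of radius %g in a %dx%d image",
                  n, radius, rows, cols)
    }
    if (s < minSpacing)
        stopf("cannot place %d non-overlapping nuclei of radius %g in a %dx%d image",
              n, radius, rows, cols)
    jit <- min(2, (s - minSpacing) / 2)
    cells <- sample(gr * gc, n)
    ci <- (cells - 1L) %% gr
    cj <- (cells - 1L) %/% gr
    data.frame(
        row = margin + ci * s + runif(n, -jit, jit),
        col = margin + cj * s + runif(n, -jit, jit))
}

# Fold x into [lo, hi] by reflection (triangle wave).
reflectInto <- function(x, lo, hi) {
    if (hi <= lo) return(rep(lo, length(x)))
    w <- hi - lo
    y <- (x - lo) %% (2 * w)
    lo + ifelse(y > w, 2 * w - y, y)
}

# Add an elliptical Gaussian of total (analytic) integral `integral`
# centred at subpixel (r0, c0) into matrix `img`, z-attenuation ignored.
addGaussianSpot <- function(img, r0, c0, sigmaY, sigmaX, integral) {
    if (integral <= 0) return(img)
    hw <- ceiling(4 * max(sigmaY, sigmaX))
    rr <- max(1L, floor(r0 + 1 - hw)):min(nrow(img), ceiling(r0 + 1 + hw))
    cc <- max(1L, floor(c0 + 1 - hw)):min(ncol(img), ceiling(c0 + 1 + hw))
    if (!length(rr) || !length(cc)) return(img)
    i0 <- integral / (2 * pi * sigmaY * sigmaX)
    gy <- exp(-((rr - 1 - r0)^2) / (2 * sigmaY^2))
    gx <- exp(-((cc - 1 - c0)^2) / (2 * sigmaX^2))
    img[rr, cc] <- img[rr, cc] + i0 * outer(gy, gx)
    img
}

# Soft-edged disk (1-px linear edge) of plateau `intensity`.
addDisk <- function(img, r0, c0, radius, intensity) {
    hw <- ceiling(radius + 1)
    rr <- max(1L, floor(r0 + 1 - hw)):min(nrow(img), ceiling(r0 + 1 + hw))
    cc <- max(1L, floor(c0 + 1 - hw)):min(ncol(img), ceiling(c0 + 1 + hw))
    d <- sqrt(outer((rr - 1 - r0)^2, (cc - 1 - c0)^2, `+`))
    img[rr, cc] <- img[rr, cc] +
        intensity * pmin(pmax(radius + 0.5 - d, 0), 1)
    img
}

applyNoise <- function(x, poissonGain, readSd) {
    if (poissonGain > 0)
        x[] <- rpois(length(x), x / poissonGain) * poissonGain
    if (readSd > 0)
        x[] <- x + rnorm(length(x), 0, readSd)
    x[x < 0] <- 0
    x
}

#' Render a synthetic two-channel movie from intensity traces
#'
#' Renders one movie: the nuclei channel shows soft-edged disks following a
#' field-wide reflected random walk (the slow stage/tissue drift of a
#' blastoderm-stage embryo; nuclei never overlap by construction), and the
#' spot channel adds, per nucleus and frame, an elliptical Gaussian
#' transcription spot whose background-subtracted integral on the brightest
#' z-plane equals the trace value before noise. Shot (Poisson) and read
#' (Gaussian) noise are applied per the scene's noise model.
#'
#' @param traces numeric matrix, one row per nucleus and one column per
#'   frame, in intensity units (the rendered spot integral).
#' @param scene a [SceneConfig]. `scene@nNuclei` must equal `nrow(traces)`.
#' @param seed RNG seed; defaults to the scene seed.
#'
#' @return list with elements `movie` (a [MovieStack]) and `truth`
#'   (a [GroundTruth]; its `onIntervals` slot is empty — promoter states are
#'   known to the simulator, see [simulateScene()]).
#'
#' @examples
#' sc <- demoScene(nNuclei = 4, frameCount = 6, imageShape = c(3, 64, 64))
#' tr <- matrix(100, 4, 6)
#' out <- renderMovie(tr, sc)
#' out$movie
#' @export
renderMovie <- function(traces, scene, seed = scene@seed) {
    stopifnot(is(scene, "SceneConfig"))
    validObject(scene)
    traces <- as.matrix(traces)
    if (nrow(traces) != scene@nNuclei)
        stopf("'traces' must have one row per nucleus (%d), got %d",
              scene@nNuclei, nrow(traces))
    if (ncol(traces) != scene@frameCount)
        stopf("trace length %d != frameCount %d", ncol(traces),
              scene@frameCount)

    nz <- scene@imageShape[1L]
    rows <- scene@imageShape[2L]
    cols <- scene@imageShape[3L]
    nf <- scene@frameCount
    n <- scene@nNuclei
    zMid <- (nz + 1L) %/% 2L
    sigmaZ <- 1.0                       # z-attenuation of the spot, planes
    margin <- scene@nucleusRadius + 5

    withSeed(seed, {
        base <- placeNuclei(n, rows, cols, scene@nucleusRadius)

        # field-wide drift, reflected so every nucleus stays in frame
        if (n > 0L) {
            stepR <- c(0, rnorm(nf - 1L, 0, scene@driftSigma))
            stepC <- c(0, rnorm(nf - 1L, 0, scene@driftSigma))
            loR <- margin - min(base$row); hiR <- rows - 1 - margin - max(base$row)
            loC <- margin - min(base$col); hiC <- cols - 1 - margin - max(base$col)
            offR <- reflectInto(cumsum(stepR), min(loR, 0), max(hiR, 0))
            offC <- reflectInto(cumsum(stepC), min(loC, 0), max(hiC, 0))
        } else {
            offR <- offC <- numeric(nf)
        }

        ms2 <- array(0, c(nf, nz, rows, cols))
        nuc <- array(0, c(nf, nz, rows, cols))
        cents <- vector("list", nf)
        spots <- vector("list", nf)

        for (f in seq_len(nf)) {
            nucPlane <- matrix(scene@backgroundLevel, rows, cols)
            ms2Plane0 <- matrix(0, rows, cols)  # spot signal, mid-z scale 1
            r <- base$row + offR[f]
            c <- base$col + offC[f]
            spotR <- r + scene@spotOffset[1L]
            spotC <- c + scene@spotOffset[2L]
            for (i in seq_len(n)) {
                nucPlane <- addDisk(nucPlane, r[i], c[i],
                                    scene@nucleusRadius,
                                    scene@nucleusIntensity)
                v <- traces[i, f]
                if (v > 0)
                    ms2Plane0 <- addGaussianSpot(ms2Plane0, spotR[i],
                                                 spotC[i], scene@psfSigma[1L],
                                                 scene@psfSigma[2L], v)
            }
            noisy <- scene@noisePoissonGain > 0 || scene@noiseReadSd > 0
            for (z in seq_len(nz)) {
                wz <- exp(-((z - zMid)^2) / (2 * sigmaZ^2))
                nucZ <- nucPlane
                ms2Z <- scene@backgroundLevel + wz * ms2Plane0
                if (noisy) {   # per-plane, keeps memory flat
                    nucZ <- applyNoise(nucZ, scene@noisePoissonGain,
                                       scene@noiseReadSd)
                    ms2Z <- applyNoise(ms2Z, scene@noisePoissonGain,
                                       scene@noiseReadSd)
                }
                nuc[f, z, , ] <- nucZ
                ms2[f, z, , ] <- ms2Z
            }
            cents[[f]] <- data.frame(frame = rep(f - 1L, n),
                                     label = seq_len(n), row = r, col = c)
            spots[[f]] <- data.frame(frame = rep(f - 1L, n),
                                     label = seq_len(n), row = spotR,
                                     col = spotC)
        }

        truthTraces <- if (n > 0L)
            data.frame(label = rep(seq_len(n), each = nf),
                       frame = rep(seq_len(nf) - 1L, n),
                       value = as.vector(t(traces)))
        else data.frame(label = integer(), frame = integer(),
                        value = numeric())

        list(
            movie = MovieStack(ms2 = ms2, nuclei = nuc,
                               frameInterval = scene@frameInterval),
            truth = new("GroundTruth",
                centroids = do.call(rbind, cents),
                traces = truthTraces,
                onIntervals = data.frame(label = integer(),
                                         start_frame = integer(),
                                         end_frame = integer()),
                spotPositions = do.call(rbind, spots)))
    })
}

#' Simulate telegraph kinetics for every nucleus and render the movie
#'
#' Convenience driver: one [simulateTelegraph()] realization per nucleus
#' (intensity = transcript count times `scene@unitIntensity`), then
#' [renderMovie()]. The returned ground truth carries the promoter-ON
#' intervals of every nucleus.
#'
#' @param scene a [SceneConfig].
#' @param seed master RNG seed; defaults to the scene seed. Per-nucleus
#'   simulation seeds are derived deterministically from it.
#' @return list with `movie` ([MovieStack]), `truth` ([GroundTruth]) and
#'   `traces` (the true intensity matrix, nuclei x frames).
#' @examples
#' sc <- demoScene(nNuclei = 4, frameCount = 20, imageShape = c(3, 64, 64))
#' sim <- simulateScene(sc)
#' sim$truth
#' @export
simulateScene <- function(scene, seed = scene@seed) {
    stopifnot(is(scene, "SceneConfig"))
    n <- scene@nNuclei
    traces <- matrix(0, n, scene@frameCount)
    onIv <- vector("list", n)
    for (i in seq_len(n)) {
        sim <- simulateTelegraph(scene@kinetics, scene@frameCount,
                                 scene@frameInterval,
                                 seed = childSeed(seed, i))
        traces[i, ] <- sim$trace * scene@unitIntensity
        if (nrow(sim$onIntervals))
            onIv[[i]] <- cbind(label = i, sim$onIntervals)
    }
    out <- renderMovie(traces, scene, seed = childSeed(seed, 0L))
    onIv <- onIv[!vapply(onIv, is.null, logical(1))]
    out$truth@onIntervals <- if (length(onIv)) do.call(rbind, onIv)
        else data.frame(label = integer(), start_frame = integer(),
                        end_frame = integer())
    out$traces <- traces
    out
}

#' Default demonstration scene
#'
#' A blastoderm-like field: 50 trackable nuclei, 200 frames at 16.8 s/frame,
#' slow field drift (0.5 px/frame), diffraction-limited spots (sigma 2 px)
#' on a nonzero background with shot and read noise.
#'
#' @param ... overrides passed to [SceneConfig()].
#' @return A [SceneConfig].
#' @examples
#' demoScene(nNuclei = 10)
#' @export
demoScene <- function(...) {
    args <- list(...)
    defaults <- list(nNuclei = 50L, frameCount = 200L, frameInterval = 16.8,
                     imageShape = c(3L, 300L, 430L), nucleusRadius = 8,
                     driftSigma = 0.5, psfSigma = c(2, 2),
                     backgroundLevel = 100, nucleusIntensity = 600,
                     unitIntensity = 40, spotOffset = c(1.7, 2.3),
                     noisePoissonGain = 1, noiseReadSd = 3,
                     kinetics = TelegraphParams(), seed = 1L)
    defaults[names(args)] <- args
    do.call(SceneConfig, defaults)
}

#' Write a synthetic movie fixture to disk
#'
#' Simulates a scene and writes: one multi-page 16-bit TIFF per channel
#' (`nuclei.tif`, `ms2.tif`; frames-major page order), the ground-truth
#' tables (`nuclei_truth.tsv`, `trace_truth.tsv`, `bursts_truth.tsv`), and
#' the resolved scene configuration (`scene.yaml`). Deterministic for a
#' given seed.
#'
#' @param scene a [SceneConfig].
#' @param outDir output directory (created if absent).
#' @param seed RNG seed; defaults to the scene seed.
#' @return Invisibly, the list returned by [simulateScene()].
#' @export
makeFixture <- function(scene, outDir, seed = scene@seed) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateScene(scene, seed = seed)
    writeMovie(sim$movie, file.path(outDir, "ms2.tif"),
               file.path(outDir, "nuclei.tif"))
    tr <- trueCentroids(sim$truth)
    writeTable(tr[, c("frame", "label", "row", "col")],
               file.path(outDir, "nuclei_truth.tsv"))
    writeTable(trueTraces(sim$truth)[, c("label", "frame", "value")],
               file.path(outDir, "trace_truth.tsv"))
    writeTable(trueOnIntervals(sim$truth),
               file.path(outDir, "bursts_truth.tsv"))
    yaml::write_yaml(sceneToList(scene, seed),
                     file.path(outDir, "scene.yaml"))
    invisible(sim)
}

sceneToList <- function(scene, seed = scene@seed) {
    k <- scene@kinetics
    list(scene = list(
        n_nuclei = scene@nNuclei, frame_count = scene@frameCount,
        frame_interval = scene@frameInterval,
        image_shape = as.integer(scene@imageShape),
        nucleus_radius = scene@nucleusRadius, drift_sigma = scene@driftSigma,
        psf_sigma = scene@psfSigma, background_level = scene@backgroundLevel,
        nucleus_intensity = scene@nucleusIntensity,
        unit_intensity = scene@unitIntensity,
        spot_offset = scene@spotOffset,
        noise = list(poisson_gain = scene@noisePoissonGain,
                     read_sd = scene@noiseReadSd),
        kinetics = list(k_on = k@kOn, k_off = k@kOff,
                        loading_rate = k@loadingRate,
                        dwell_time = k@dwellTime),
        seed = as.integer(seed)))
}

sceneFromList <- function(x) {
    s <- x$scene
    kin <- TelegraphParams(kOn = s$kinetics$k_on, kOff = s$kinetics$k_off,
                           loadingRate = s$kinetics$loading_rate,
                           dwellTime = s$kinetics$dwell_time)
    SceneConfig(nNuclei = s$n_nuclei, frameCount = s$frame_count,
                frameInterval = s$frame_interval,
                imageShape = s$image_shape,
                nucleusRadius = s$nucleus_radius,
                driftSigma = s$drift_sigma, psfSigma = s$psf_sigma,
                backgroundLevel = s$background_level,
                nucleusIntensity = s$nucleus_intensity,
                unitIntensity = s$unit_intensity,
                spotOffset = s$spot_offset,
                noisePoissonGain = s$noise$poisson_gain,
                noiseReadSd = s$noise$read_sd,
                kinetics = kin, seed = s$seed)
}
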