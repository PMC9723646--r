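pipelineSections <- c("seed", "control", "scene", "conditions",
                      "segmentation", "tracking", "burst", "output")

#' Read and validate a pipeline configuration
#'
#' The YAML configuration mirrors the pipeline stages: a base `scene`, a
#' named `conditions` map (per-condition telegraph kinetics overriding the
#' base scene, or `ms2`/`nuclei`/`nz` paths to recorded movies), and
#' `segmentation`, `tracking` and `burst` sections. Unknown keys are
#' rejected, and all values are validated before any computation starts.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return The resolved configuration (defaults applied) as a list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (is.character(path)) yaml::read_yaml(path) else path
    unknown <- setdiff(names(cfg), pipelineSections)
    if (length(unknown))
        stopf("unknown configuration key(s): %s",
              paste(unknown, collapse = ", "))
    checkKeys <- function(x, allowed, where) {
        bad <- setdiff(names(x), allowed)
        if (length(bad))
            stopf("unknown key(s) in '%s': %s", where,
                  paste(bad, collapse = ", "))
    }
    checkKeys(cfg$segmentation,
              c("blur_sigma", "bright_tail_fraction", "bright_mode",
                "expected_count", "size_bounds", "crop_box",
                "min_region_size"), "segmentation")
    checkKeys(cfg$tracking, c("max_displacement", "min_track_length"),
              "tracking")
    checkKeys(cfg$burst,
              c("smooth_window", "start_threshold", "end_fraction",
                "min_duration", "shift", "decreasing_start_len"), "burst")

    cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
    if (is.null(cfg$conditions) || !length(cfg$conditions))
        stopf("'conditions' must name at least one condition")
    if (is.null(cfg$control)) cfg$control <- names(cfg$conditions)[1L]
    if (!(cfg$control %in% names(cfg$conditions)))
        stopf("control condition '%s' not among conditions", cfg$control)

    b <- cfg$burst
    cfg$burstConfig <- BurstCallConfig(
        smoothWindow = b$smooth_window %||% 5L,
        startThreshold = b$start_threshold %||% NA_real_,
        endFraction = b$end_fraction %||% 0.55,
        minDuration = b$min_duration %||% 5L,
        shift = b$shift %||% 2L,
        decreasingStartLen = b$decreasing_start_len %||%
            (b$smooth_window %||% 5L))
    validObject(cfg$burstConfig)

    s <- cfg$segmentation
    cfg$segConfig <- segmentationConfig(
        blurSigma = s$blur_sigma %||% 2,
        brightTailFraction = s$bright_tail_fraction %||% 0.05,
        brightMode = s$bright_mode %||% "quantile",
        expectedCount = unlist(s$expected_count %||% c(1, Inf)),
        sizeBounds = unlist(s$size_bounds %||% c(20, Inf)),
        cropBox = s$crop_box,
        minRegionSize = s$min_region_size %||% 20)

    cfg$maxDisplacement <- cfg$tracking$max_displacement %||% 8
    cfg$minTrackLength <- cfg$tracking$min_track_length %||% 1L
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve the scene for one condition: base scene + kinetics overrides.
conditionScene <- function(cfg, condName, seed) {
    base <- cfg$scene %||% list()
    cond <- cfg$conditions[[condName]]
    sceneKeys <- c(n_nuclei = "nNuclei", frame_count = "frameCount",
                   frame_interval = "frameInterval",
                   image_shape = "imageShape",
                   nucleus_radius = "nucleusRadius",
                   drift_sigma = "driftSigma", psf_sigma = "psfSigma",
                   background_level = "backgroundLevel",
                   nucleus_intensity = "nucleusIntensity",
                   unit_intensity = "unitIntensity",
                   spot_offset = "spotOffset",
                   noise_poisson_gain = "noisePoissonGain",
                   noise_read_sd = "noiseReadSd")
    bad <- setdiff(names(base), names(sceneKeys))
    if (length(bad))
        stopf("unknown key(s) in 'scene': %s", paste(bad, collapse = ", "))
    args <- base
    names(args) <- sceneKeys[names(base)]
    args <- lapply(args, unlist)
    scn <- do.call(demoScene, args)
    kin <- scn@kinetics
    if (!is.null(cond$k_on)) kin@kOn <- cond$k_on
    if (!is.null(cond$k_off)) kin@kOff <- cond$k_off
    if (!is.null(cond$loading_rate)) kin@loadingRate <- cond$loading_rate
    if (!is.null(cond$dwell_time)) kin@dwellTime <- cond$dwell_time
    scn@kinetics <- kin
    scn@seed <- as.integer(seed)
    scn
}

#' Run the full analysis pipeline
#'
#' For every condition: obtain a movie (simulated from the configured scene
#' and kinetics, or read from the configured TIFF paths), segment nuclei,
#' track them, extract spot traces, and call bursts. Then compare all
#' conditions against the control and render the report. Every
#' intermediate table, a per-frame QC log, the resolved configuration and
#' a version stamp are written to `outDir`; reruns with identical
#' configuration and seed reproduce identical tables.
#'
#' @param config path to a YAML configuration or a list (see
#'   [readPipelineConfig()]).
#' @param outDir output directory.
#' @param seed overrides the configured seed when not `NULL`.
#' @return Invisibly, a list with the per-condition results and the
#'   comparison table.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
    cfg <- readPipelineConfig(config)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    condNames <- names(cfg$conditions)
    results <- list()
    summaries <- list()
    traceSets <- list()
    for (ci in seq_along(condNames)) {
        cn <- condNames[ci]
        cdir <- file.path(outDir, cn)
        dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
        cond <- cfg$conditions[[cn]]
        stage <- function(name, expr) {
            tryCatch(expr, error = function(e)
                stopf("[%s/%s] %s", cn, name, conditionMessage(e)))
        }
        movie <- stage("input", {
            if (!is.null(cond$ms2)) {
                readMovie(cond$ms2, cond$nuclei, nz = cond$nz %||% 1L)
            } else {
                scn <- conditionScene(cfg, cn, childSeed(cfg$seed, ci))
                sim <- simulateScene(scn)
                writeTable(trueCentroids(sim$truth),
                           file.path(cdir, "nuclei_truth.tsv"))
                writeTable(trueOnIntervals(sim$truth),
                           file.path(cdir, "bursts_truth.tsv"))
                sim$movie
            }
        })
        seg <- stage("segmentation", segmentMovie(movie, cfg$segConfig))
        writeTable(regionTable(seg), file.path(cdir, "regions.tsv"))
        writeTable(qcTable(seg), file.path(cdir, "qc.tsv"))
        tracks <- stage("tracking",
                        trackMovie(seg, cfg$maxDisplacement,
                                   cfg$minTrackLength))
        writeTable(tracks, file.path(cdir, "tracks.tsv"))
        traces <- stage("extraction", extractTraces(movie, seg, tracks))
        writeTable(traceTable(traces), file.path(cdir, "traces.tsv"))
        writeTable(spotFits(traces), file.path(cdir, "spotfits.tsv"))
        bursts <- stage("bursts", summarizeBursts(traces, cfg$burstConfig))
        writeTable(bursts$bursts, file.path(cdir, "bursts.tsv"))
        writeTable(bursts$summary, file.path(cdir, "summary.tsv"))
        results[[cn]] <- list(seg = seg, tracks = tracks, traces = traces,
                              bursts = bursts)
        summaries[[cn]] <- cbind(condition = cn, bursts$summary)
        traceSets[[cn]] <- traces
    }

    comparisons <- NULL
    if (length(condNames) >= 2L) {
        allSum <- do.call(rbind, summaries)
        comparisons <- compareConditions(allSum, cfg$control)
        renderReport(comparisons, traceSets, allSum, outDir,
                     cfg$burstConfig)
    }

    resolved <- cfg[intersect(pipelineSections, names(cfg))]
    yaml::write_yaml(resolved, file.path(outDir, "resolved_config.yaml"))
    writeLines(paste("ms2burst",
                     as.character(utils::packageVersion("ms2burst"))),
               file.path(outDir, "VERSION"))
    invisible(list(results = results, comparisons = comparisons,
                   outDir = outDir))
}
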