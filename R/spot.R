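#' Locate the brightest voxel of a nucleus
#'
#' Returns the argmax of intensity over the nucleus's territory across all
#' z-planes; ties are broken toward the lowest (z, row, col).
#'
#' @param ms2Frame 3-D array (z, row, col), one time frame of the spot
#'   channel (in the same cropped coordinates as `region`).
#' @param region logical matrix (rows x cols) marking the nucleus
#'   territory; must contain at least one pixel.
#' @return list: `z`, `row`, `col` (1-based indices into `ms2Frame`) and
#'   `value`.
#' @export
locateBrightestVoxel <- function(ms2Frame, region) {
    idx <- which(region)
    if (!length(idx)) stopf("empty region")
    pos <- which(region, arr.ind = TRUE)
    # row-major tie order within a plane: sort candidates by (row, col)
    ord <- order(pos[, 1L], pos[, 2L])
    pos <- pos[ord, , drop = FALSE]
    idx <- idx[ord]
    best <- NULL
    for (z in seq_len(dim(ms2Frame)[1L])) {
        plane <- ms2Frame[z, , ]
        v <- plane[idx]
        i <- which.max(v)       # first max = lowest (row, col)
        if (is.null(best) || v[i] > best$value)
            best <- list(z = z, row = unname(pos[i, 1L]),
                         col = unname(pos[i, 2L]), value = unname(v[i]))
    }
    best
}

#' Fit a 2-D elliptical Gaussian with constant local background
#'
#' Ordinary (unweighted) nonlinear least squares of
#' `I(x, y) = alpha + I0 * exp(-((x - x0)^2 / (2 sigma_x^2) +
#' (y - y0)^2 / (2 sigma_y^2)))` on a pixel window (nominally 11 x 11,
#' centred on the brightest voxel; edge-truncated windows of at least
#' 7 x 7 pixels are fitted and flagged). The background-subtracted spot
#' intensity is the analytic integral `2 * pi * sigma_x * sigma_y * I0`.
#'
#' A fit is accepted (`fit_ok`) when the optimizer converges with
#' `I0 > 0`, both spreads strictly inside `[0.3, 6]` px, and the centre
#' inside the window; otherwise the record carries `integral = 0`.
#'
#' @param window 2-D numeric matrix (rows = y, cols = x).
#' @param init optional named list overriding the default initialization
#'   (`alpha` = window median, `i0` = max - median, centre of window,
#'   `sigma` = 1.5 px).
#' @return list: `alpha`, `i0`, `x0`, `y0` (0-based window coordinates),
#'   `sigma_x`, `sigma_y`, `integral`, `fit_ok`, `truncated`.
#' @examples
#' g <- outer(0:10, 0:10, function(y, x)
#'     10 + 100 * exp(-((x - 5)^2 + (y - 5)^2) / (2 * 1.5^2)))
#' fit <- fitGaussian2d(g)
#' all.equal(fit$integral, 2 * pi * 1.5^2 * 100, tolerance = 1e-4)
#' @export
fitGaussian2d <- function(window, init = NULL) {
    if (any(!is.finite(window))) stopf("non-finite pixels in fit window")
    nr <- nrow(window); nc <- ncol(window)
    failed <- list(alpha = NA_real_, i0 = NA_real_, x0 = NA_real_,
                   y0 = NA_real_, sigma_x = NA_real_, sigma_y = NA_real_,
                   integral = 0, fit_ok = FALSE,
                   truncated = (nr != 11L || nc != 11L))
    if (nr < 7L || nc < 7L) return(failed)
    if (diff(range(window)) <= 0) return(failed)   # featureless window

    med <- median(window)
    p0 <- c(alpha = med, i0 = max(window) - med, x0 = (nc - 1) / 2,
            y0 = (nr - 1) / 2, sx = 1.5, sy = 1.5)
    if (!is.null(init)) {
        if (!is.null(init$alpha)) p0["alpha"] <- init$alpha
        if (!is.null(init$i0)) p0["i0"] <- init$i0
        if (!is.null(init$x0)) p0["x0"] <- init$x0
        if (!is.null(init$y0)) p0["y0"] <- init$y0
        if (!is.null(init$sigma_x)) p0["sx"] <- init$sigma_x
        if (!is.null(init$sigma_y)) p0["sy"] <- init$sigma_y
    }
    if (!all(is.finite(p0))) stopf("non-finite fit initialization")
    p0["i0"] <- max(p0["i0"], 1e-6)

    x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    y <- matrix(0:(nr - 1), nr, nc)
    resid <- function(p) {
        mu <- p[1L] + p[2L] * exp(-((x - p[3L])^2 / (2 * p[5L]^2) +
                                    (y - p[4L])^2 / (2 * p[6L]^2)))
        as.vector(mu - window)
    }
    lower <- c(-Inf, 0, 0, 0, 0.3, 0.3)
    upper <- c(Inf, Inf, nc - 1, nr - 1, 6, 6)
    fit <- tryCatch(
        suppressWarnings(
            minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                               fn = resid,
                               control = minpack.lm::nls.lm.control(
                                   maxiter = 100))),
        error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) return(failed)
    p <- fit$par
    eps <- 1e-3
    ok <- p[2L] > 1e-8 &&
        p[5L] > 0.3 + eps && p[5L] < 6 - eps &&
        p[6L] > 0.3 + eps && p[6L] < 6 - eps &&
        p[3L] >= 0 && p[3L] <= nc - 1 && p[4L] >= 0 && p[4L] <= nr - 1
    if (!ok) return(failed)
    list(alpha = unname(p[1L]), i0 = unname(p[2L]), x0 = unname(p[3L]),
         y0 = unname(p[4L]), sigma_x = unname(p[5L]),
         sigma_y = unname(p[6L]),
         integral = unname(2 * pi * p[5L] * p[6L] * p[2L]),
         fit_ok = TRUE, truncated = (nr != 11L || nc != 11L))
}

# 11x11 window around (row, col) on one plane, truncated at image edges.
fitWindow <- function(plane, row, col, half = 5L) {
    rr <- max(1L, row - half):min(nrow(plane), row + half)
    cc <- max(1L, col - half):min(ncol(plane), col + half)
    list(window = plane[rr, cc, drop = FALSE],
         rowOffset = rr[1L] - 1L, colOffset = cc[1L] - 1L)
}

#' Extract per-track transcription traces from a movie
#'
#' For every tracked nucleus and frame: locate the brightest voxel within
#' the nucleus's Voronoi territory across all z-sections, fit an 11 x 11
#' 2-D Gaussian with local background on that single z-plane
#' ([fitGaussian2d()]), and record the background-subtracted integral.
#' Failed fits contribute an integral of 0; frames where the track is
#' absent are recorded as missing (`NA`) and excluded from the baseline.
#' Each assembled trajectory is then baseline-zeroed by subtracting its
#' minimum over valid frames.
#'
#' @param movie a [MovieStack] (full-frame; the segmentation crop box is
#'   applied internally).
#' @param seg the [SegmentedMovie] the tracks were built from.
#' @param tracks track table from [trackMovie()].
#' @return A [TraceSet].
#' @export
extractTraces <- function(movie, seg, tracks) {
    stopifnot(is(movie, "MovieStack"), is(seg, "SegmentedMovie"))
    if (!nrow(tracks))
        return(new("TraceSet",
                   traces = data.frame(track_id = integer(),
                                       frame = integer(), raw = numeric(),
                                       baseline_subtracted = numeric(),
                                       fit_ok = logical(),
                                       missing = logical()),
                   fits = data.frame(),
                   frameInterval = frameInterval(movie)))
    box <- cropBox(seg)
    nz <- dim(movie@ms2)[2L]

    recs <- vector("list", nrow(tracks))
    fitRecs <- vector("list", nrow(tracks))
    k <- 0L
    for (f in sort(unique(tracks$frame))) {
        terr <- territoryImages(seg)[[f + 1L]]
        stack <- frameStack(movie@ms2, f + 1L)
        cropped <- array(0, c(nz, box[3L], box[4L]))
        for (z in seq_len(nz))
            cropped[z, , ] <- cropFrame(stack[z, , ], box)
        pixByLabel <- split(which(terr > 0L), terr[terr > 0L])
        rows <- tracks[tracks$frame == f, ]
        for (i in seq_len(nrow(rows))) {
            lab <- rows$label[i]
            pix <- pixByLabel[[as.character(lab)]]
            mask <- matrix(FALSE, nrow(terr), ncol(terr))
            mask[pix] <- TRUE
            bv <- locateBrightestVoxel(cropped, mask)
            w <- fitWindow(cropped[bv$z, , ], bv$row, bv$col)
            fit <- fitGaussian2d(w$window)
            k <- k + 1L
            recs[[k]] <- data.frame(track_id = rows$track_id[i], frame = f,
                                    raw = fit$integral, fit_ok = fit$fit_ok)
            fitRecs[[k]] <- data.frame(
                track_id = rows$track_id[i], frame = f,
                z_index = bv$z - 1L,
                x0 = if (fit$fit_ok) fit$x0 + w$colOffset else NA_real_,
                y0 = if (fit$fit_ok) fit$y0 + w$rowOffset else NA_real_,
                alpha = fit$alpha, i0 = fit$i0, sigma_x = fit$sigma_x,
                sigma_y = fit$sigma_y, integral = fit$integral,
                fit_ok = fit$fit_ok)
        }
    }
    tab <- do.call(rbind, recs[seq_len(k)])
    fits <- do.call(rbind, fitRecs[seq_len(k)])

    # fill missing frames within each track span, then baseline-zero
    out <- lapply(split(tab, tab$track_id), function(d) {
        span <- min(d$frame):max(d$frame)
        full <- data.frame(track_id = d$track_id[1L], frame = span)
        m <- match(full$frame, d$frame)
        full$raw <- d$raw[m]
        full$fit_ok <- d$fit_ok[m]
        full$missing <- is.na(m)
        full$fit_ok[full$missing] <- FALSE
        base <- min(full$raw[!full$missing])
        full$baseline_subtracted <- full$raw - base
        full
    })
    traces <- do.call(rbind, out)
    traces <- traces[order(traces$track_id, traces$frame),
                     c("track_id", "frame", "raw", "baseline_subtracted",
                       "fit_ok", "missing")]
    rownames(traces) <- NULL
    new("TraceSet", traces = traces, fits = fits,
        frameInterval = frameInterval(movie))
}
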