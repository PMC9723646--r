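#' Maximum-intensity projection of a z-stack
#'
#' @param stackFrame 3-D array (z, row, col) with at least one z-plane.
#' @return 2-D matrix, per-pixel maximum over z.
#' @examples
#' maxProject(array(1:8, c(2, 2, 2)))
#' @export
maxProject <- function(stackFrame) {
    d <- dim(stackFrame)
    if (is.null(d) || length(d) != 3L || d[1L] < 1L)
        stopf("'stackFrame' must be a 3-D (z, row, col) array with >= 1 plane")
    apply(stackFrame, c(2L, 3L), max)
}

#' Crop a 2-D image to a 0-based half-open box
#'
#' @param image 2-D matrix.
#' @param box integer(4): (row0, col0, rows, cols); 0-based origin,
#'   half-open extent.
#' @return The exact sub-image.
#' @export
cropFrame <- function(image, box) {
    box <- as.integer(box)
    if (length(box) != 4L) stopf("'box' must be (row0, col0, rows, cols)")
    r0 <- box[1L]; c0 <- box[2L]; nr <- box[3L]; nc <- box[4L]
    if (r0 < 0L || c0 < 0L || nr < 1L || nc < 1L ||
        r0 + nr > nrow(image) || c0 + nc > ncol(image))
        stopf("crop box (%d,%d,%d,%d) out of bounds for %dx%d image",
              r0, c0, nr, nc, nrow(image), ncol(image))
    image[(r0 + 1L):(r0 + nr), (c0 + 1L):(c0 + nc), drop = FALSE]
}

# Default crop rule: centred 300x430 on 512x512 inputs, else full frame.
defaultCropBox <- function(rows, cols) {
    if (rows == 512L && cols == 512L) {
        c((512L - 300L) %/% 2L, (512L - 430L) %/% 2L, 300L, 430L)
    } else {
        c(0L, 0L, rows, cols)
    }
}

#' Preprocess the nuclei channel: Gaussian blur and bright-tail clipping
#'
#' Blurs the image and suppresses the brightest pixels (typically
#' transcription-dot bleed-through or debris). Two removal semantics are
#' offered: `"quantile"` (default) clips the brightest `brightTailFraction`
#' of pixels to the corresponding quantile value; `"max_fraction"` clips
#' pixels brighter than `(1 - brightTailFraction)` of the global maximum.
#'
#' @param image 2-D matrix.
#' @param blurSigma Gaussian blur sigma in pixels; 0 disables blurring.
#' @param brightTailFraction fraction in `[0, 1)`; 0 disables clipping.
#' @param mode `"quantile"` or `"max_fraction"`.
#' @return Preprocessed 2-D matrix.
#' @export
preprocessNuclei <- function(image, blurSigma = 2,
                             brightTailFraction = 0.05,
                             mode = c("quantile", "max_fraction")) {
    mode <- match.arg(mode)
    if (blurSigma < 0) stopf("'blurSigma' must be >= 0")
    if (brightTailFraction < 0 || brightTailFraction >= 1)
        stopf("'brightTailFraction' must be in [0, 1)")
    out <- image
    if (blurSigma > 0)
        out <- as.matrix(EBImage::gblur(out, sigma = blurSigma))
    if (brightTailFraction > 0) {
        cut <- if (mode == "quantile")
            quantile(out, 1 - brightTailFraction, names = FALSE)
        else (1 - brightTailFraction) * max(out)
        out[out > cut] <- cut
    }
    out
}

# Otsu threshold on a numeric matrix (256-bin histogram).
otsuThreshold <- function(image) {
    lo <- min(image); hi <- max(image)
    if (hi <= lo) return(lo)
    scaled <- (image - lo) / (hi - lo)
    t <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
    lo + t * (hi - lo)
}

#' Threshold a frame adaptively by component count and size
#'
#' Scans candidate thresholds (the 5th-95th percentiles of the image in
#' 1-percentile steps) and keeps the binarization whose connected-component
#' count falls within `expectedCount` and whose median component area falls
#' within `sizeBounds`. Ties are broken toward the candidate nearest the
#' Otsu threshold. If no candidate satisfies both criteria the best-scoring
#' one is returned and the frame is flagged as degraded.
#'
#' @param image 2-D matrix (typically from [preprocessNuclei()]).
#' @param expectedCount numeric(2), acceptable (min, max) component count.
#' @param sizeBounds numeric(2), acceptable (min, max) median component
#'   area in pixels.
#' @return list: `mask` (logical matrix), `threshold`, `nComponents`,
#'   `medianArea`, `degraded`.
#' @export
adaptiveThreshold <- function(image, expectedCount = c(1, Inf),
                              sizeBounds = c(20, Inf)) {
    if (expectedCount[1L] > expectedCount[2L] ||
        sizeBounds[1L] > sizeBounds[2L])
        stopf("'expectedCount' and 'sizeBounds' must satisfy min <= max")
    if (max(image) <= min(image)) {
        return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                    threshold = NA_real_, nComponents = 0L,
                    medianArea = NA_real_, degraded = TRUE))
    }
    cands <- unique(quantile(image, seq(0.05, 0.95, by = 0.01),
                             names = FALSE))
    otsu <- otsuThreshold(image)
    best <- NULL
    for (t in cands) {
        mask <- image > t
        lab <- EBImage::bwlabel(mask)
        n <- max(lab)
        if (n == 0L) {
            score <- 0L; med <- NA_real_
        } else {
            med <- median(tabulate(lab[lab > 0L]))
            score <- (n >= expectedCount[1L] && n <= expectedCount[2L]) +
                (med >= sizeBounds[1L] && med <= sizeBounds[2L])
        }
        cand <- list(mask = mask, threshold = t, nComponents = as.integer(n),
                     medianArea = med, score = score,
                     otsuDist = abs(t - otsu))
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score && cand$otsuDist < best$otsuDist))
            best <- cand
    }
    list(mask = best$mask, threshold = best$threshold,
         nComponents = best$nComponents, medianArea = best$medianArea,
         degraded = best$score < 2L)
}

#' Detect candidate transcription dots in an MS2 projection
#'
#' A pixel belongs to a dot when its intensity exceeds twice the frame mean;
#' dots are the connected components of that mask.
#'
#' @param ms2Projection 2-D matrix (max projection of the spot channel).
#' @return list: `mask` (logical), `centroids` (data.frame `label`, `row`,
#'   `col`; 0-based subpixel centroids).
#' @export
detectMs2Dots <- function(ms2Projection) {
    if (!length(ms2Projection)) stopf("empty image")
    mask <- ms2Projection > 2 * mean(ms2Projection)
    lab <- EBImage::bwlabel(mask)
    n <- max(lab)
    if (n == 0L)
        return(list(mask = mask,
                    centroids = data.frame(label = integer(),
                                           row = numeric(),
                                           col = numeric())))
    idx <- which(lab > 0L, arr.ind = TRUE)
    l <- lab[lab > 0L]
    cent <- data.frame(
        label = seq_len(n),
        row = tapply(idx[, 1L] - 1, l, mean),
        col = tapply(idx[, 2L] - 1, l, mean))
    rownames(cent) <- NULL
    list(mask = mask, centroids = cent)
}

# Boundary pixels of a label image: labelled pixels with a 4-neighbour
# outside their region. Returns data.frame(label, row, col) 1-based indices.
boundaryPixels <- function(labels) {
    nr <- nrow(labels); nc <- ncol(labels)
    pad <- matrix(0L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
    ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
    isBnd <- ctr > 0L & (
        pad[1:nr, 2:(nc + 1L)] != ctr | pad[3:(nr + 2L), 2:(nc + 1L)] != ctr |
        pad[2:(nr + 1L), 1:nc] != ctr | pad[2:(nr + 1L), 3:(nc + 2L)] != ctr)
    idx <- which(isBnd, arr.ind = TRUE)
    data.frame(label = ctr[isBnd], row = idx[, 1L], col = idx[, 2L])
}

#' Attach stray transcription dots to their nearest nucleus
#'
#' Every dot centroid must end up inside a nucleus region. A dot that falls
#' outside all regions is captured by the region whose boundary pixel is
#' nearest (Euclidean distance; ties to the lower label): the region is
#' dilated along the straight path from that boundary pixel to the dot.
#' Region disjointness is preserved (only background pixels are rewritten).
#'
#' @param labels integer label matrix (0 = background).
#' @param dots data.frame of dot centroids (`row`, `col`; 0-based) as from
#'   [detectMs2Dots()].
#' @return Corrected integer label matrix.
#' @export
attachDots <- function(labels, dots) {
    if (!nrow(dots)) return(labels)
    if (max(labels) == 0L) {
        warning("no nuclei in frame; transcription dots left unassigned")
        return(labels)
    }
    bnd <- NULL
    for (k in seq_len(nrow(dots))) {
        dr <- dots$row[k] + 1; dc <- dots$col[k] + 1   # 1-based
        pr <- min(max(round(dr), 1L), nrow(labels))
        pc <- min(max(round(dc), 1L), ncol(labels))
        if (labels[pr, pc] > 0L) next                  # already inside
        if (is.null(bnd)) bnd <- boundaryPixels(labels)
        d2 <- (bnd$row - dr)^2 + (bnd$col - dc)^2
        # nearest boundary pixel; ties: lower label, then row/col order
        ord <- order(d2, bnd$label, bnd$row, bnd$col)
        hit <- ord[1L]
        lab <- bnd$label[hit]
        # rasterize the straight path boundary pixel -> dot
        nstep <- max(2L, 2L * ceiling(sqrt(d2[hit])) + 1L)
        tt <- seq(0, 1, length.out = nstep)
        rr <- round(bnd$row[hit] + tt * (dr - bnd$row[hit]))
        cc <- round(bnd$col[hit] + tt * (dc - bnd$col[hit]))
        ok <- rr >= 1L & rr <= nrow(labels) & cc >= 1L & cc <= ncol(labels)
        for (i in which(ok)) {
            if (labels[rr[i], cc[i]] == 0L) labels[rr[i], cc[i]] <- lab
        }
        bnd <- NULL                                    # labels changed
    }
    labels
}

#' Nearest-centroid (Voronoi) partition of an image
#'
#' Assigns every pixel to the nearest centroid (Euclidean distance in pixel
#' units; ties to the lower label). The resulting cell of each nucleus is
#' its measurement territory for spot extraction.
#'
#' @param centroids data.frame with columns `label`, `row`, `col`
#'   (0-based, subpixel allowed).
#' @param imageShape integer(2): (rows, cols).
#' @return Integer matrix of cell labels.
#' @export
voronoiPartition <- function(centroids, imageShape) {
    if (!nrow(centroids)) stopf("'centroids' must contain >= 1 centroid")
    nr <- imageShape[1L]; nc <- imageShape[2L]
    rowg <- matrix(0:(nr - 1L), nr, nc)
    colg <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)
    ord <- order(centroids$label)
    best <- matrix(Inf, nr, nc)
    cell <- matrix(0L, nr, nc)
    for (i in ord) {
        d2 <- (rowg - centroids$row[i])^2 + (colg - centroids$col[i])^2
        upd <- d2 < best            # strict: first (lower) label wins ties
        best[upd] <- d2[upd]
        cell[upd] <- centroids$label[i]
    }
    cell
}

# Region records (0-based centroids, areas) from a label image.
regionRecords <- function(labels) {
    n <- max(labels)
    if (n == 0L)
        return(data.frame(label = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), area = integer()))
    idx <- which(labels > 0L, arr.ind = TRUE)
    l <- labels[labels > 0L]
    out <- data.frame(
        label = sort(unique(l)),
        centroid_row = as.numeric(tapply(idx[, 1L] - 1, l, mean)),
        centroid_col = as.numeric(tapply(idx[, 2L] - 1, l, mean)),
        area = as.integer(tapply(l, l, length)))
    rownames(out) <- NULL
    out
}

# Drop components smaller than minSize and relabel 1..n preserving order.
filterSmall <- function(labels, minSize) {
    if (max(labels) == 0L) return(labels)
    areas <- tabulate(labels[labels > 0L])
    keep <- which(areas >= minSize)
    map <- integer(length(areas))
    map[keep] <- seq_along(keep)
    out <- labels
    out[out > 0L] <- map[out[out > 0L]]
    out
}

#' Default segmentation configuration
#'
#' @param blurSigma,brightTailFraction,brightMode see [preprocessNuclei()].
#' @param expectedCount,sizeBounds see [adaptiveThreshold()].
#' @param cropBox 0-based (row0, col0, rows, cols) crop, or `NULL` for the
#'   default rule (centred 300x430 on 512x512 inputs, else full frame).
#' @param minRegionSize components smaller than this (px) are discarded.
#' @param maskOverride optional list of user-supplied label matrices, one
#'   per frame (`NULL` entries fall back to the automatic result); replaces
#'   interactive manual correction.
#' @return A named list of settings for [segmentMovie()].
#' @export
segmentationConfig <- function(blurSigma = 2, brightTailFraction = 0.05,
                               brightMode = "quantile",
                               expectedCount = c(1, Inf),
                               sizeBounds = c(20, Inf), cropBox = NULL,
                               minRegionSize = 20, maskOverride = NULL) {
    list(blurSigma = blurSigma, brightTailFraction = brightTailFraction,
         brightMode = brightMode, expectedCount = expectedCount,
         sizeBounds = sizeBounds, cropBox = cropBox,
         minRegionSize = minRegionSize, maskOverride = maskOverride)
}

#' Segment nuclei in every frame of a movie
#'
#' Per frame: maximum z-projection of the nuclei channel, crop, blur and
#' bright-tail clipping, adaptive thresholding, connected-component
#' labelling with a small-object filter, dot-aware boundary correction
#' ([attachDots()] using the MS2 channel projection), and a Voronoi
#' partition of the frame from the nucleus centroids (the measurement
#' territories used downstream).
#'
#' @param movie a [MovieStack].
#' @param config a list from [segmentationConfig()].
#' @return A [SegmentedMovie].
#' @seealso [trackMovie()], [extractTraces()]
#' @export
segmentMovie <- function(movie, config = segmentationConfig()) {
    stopifnot(is(movie, "MovieStack"))
    nf <- nFrames(movie)
    d <- dim(movie@nuclei)
    box <- if (is.null(config$cropBox)) defaultCropBox(d[3L], d[4L])
           else as.integer(config$cropBox)

    labelsL <- vector("list", nf)
    terrL <- vector("list", nf)
    regionsL <- vector("list", nf)
    qcL <- vector("list", nf)

    for (f in seq_len(nf)) {
        res <- tryCatch({
            nucProj <- cropFrame(maxProject(frameStack(movie@nuclei, f)), box)
            ms2Proj <- cropFrame(maxProject(frameStack(movie@ms2, f)), box)
            ov <- config$maskOverride[[f]]
            if (!is.null(ov)) {
                labels <- ov
                at <- list(threshold = NA_real_, degraded = FALSE)
            } else {
                pre <- preprocessNuclei(nucProj, config$blurSigma,
                                        config$brightTailFraction,
                                        config$brightMode)
                at <- adaptiveThreshold(pre, config$expectedCount,
                                        config$sizeBounds)
                labels <- EBImage::bwlabel(at$mask)
                labels <- filterSmall(labels, config$minRegionSize)
            }
            dots <- detectMs2Dots(ms2Proj)
            labels <- attachDots(labels, dots$centroids)
            reg <- regionRecords(labels)
            terr <- if (nrow(reg))
                voronoiPartition(data.frame(label = reg$label,
                                            row = reg$centroid_row,
                                            col = reg$centroid_col),
                                 dim(labels))
            else matrix(0L, nrow(labels), ncol(labels))
            list(labels = labels, terr = terr, reg = reg,
                 qc = data.frame(frame = f - 1L,
                                 n_components = nrow(reg),
                                 threshold = at$threshold,
                                 degraded = isTRUE(at$degraded) ||
                                     nrow(reg) == 0L))
        }, error = function(e)
            stopf("segmentation failed at frame %d: %s", f - 1L,
                  conditionMessage(e)))
        labelsL[[f]] <- res$labels
        terrL[[f]] <- res$terr
        regionsL[[f]] <- if (nrow(res$reg)) cbind(frame = f - 1L, res$reg)
                         else NULL
        qcL[[f]] <- res$qc
    }

    regions <- do.call(rbind, regionsL[!vapply(regionsL, is.null,
                                               logical(1))])
    if (is.null(regions))
        regions <- data.frame(frame = integer(), label = integer(),
                              centroid_row = numeric(),
                              centroid_col = numeric(), area = integer())
    new("SegmentedMovie", labels = labelsL, territories = terrL,
        regions = regions, qc = do.call(rbind, qcL),
        cropBox = as.integer(box))
}
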