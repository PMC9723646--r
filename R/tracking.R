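#' Link nuclei between two consecutive frames
#'
#' Builds a one-to-one matching between previous-frame and current-frame
#' centroids greedily in ascending distance order; candidate pairs farther
#' apart than `maxDisplacement` are never matched. Ties in distance are
#' broken toward the lower previous-frame label.
#'
#' @param prevCentroids,currCentroids data.frames with columns `label`,
#'   `row`, `col` (0-based, possibly empty).
#' @param maxDisplacement maximum linkable displacement in pixels (> 0).
#' @return data.frame with columns `prev_label`, `curr_label`, `distance`.
#' @export
linkFrames <- function(prevCentroids, currCentroids, maxDisplacement) {
    if (maxDisplacement <= 0) stopf("'maxDisplacement' must be > 0")
    empty <- data.frame(prev_label = integer(), curr_label = integer(),
                        distance = numeric())
    np <- nrow(prevCentroids); nc <- nrow(currCentroids)
    if (!np || !nc) return(empty)
    d <- sqrt(outer(prevCentroids$row, currCentroids$row, `-`)^2 +
              outer(prevCentroids$col, currCentroids$col, `-`)^2)
    cand <- which(d <= maxDisplacement, arr.ind = TRUE)
    if (!nrow(cand)) return(empty)
    ord <- order(d[cand], prevCentroids$label[cand[, 1L]],
                 currCentroids$label[cand[, 2L]])
    cand <- cand[ord, , drop = FALSE]
    usedP <- logical(np); usedC <- logical(nc)
    out <- vector("list", min(np, nc))
    k <- 0L
    for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1L]; q <- cand[i, 2L]
        if (usedP[p] || usedC[q]) next
        usedP[p] <- TRUE; usedC[q] <- TRUE
        k <- k + 1L
        out[[k]] <- data.frame(prev_label = prevCentroids$label[p],
                               curr_label = currCentroids$label[q],
                               distance = d[p, q])
        if (all(usedP) || all(usedC)) break
    }
    do.call(rbind, out[seq_len(k)])
}

#' Track segmented nuclei through a movie
#'
#' Chains [linkFrames()] over consecutive frames: matched nuclei inherit
#' the track id of their predecessor, unmatched nuclei start new tracks,
#' and unmatched predecessors terminate (no gap closing).
#'
#' @param seg a [SegmentedMovie] (or a region data.frame with columns
#'   `frame`, `label`, `centroid_row`, `centroid_col`).
#' @param maxDisplacement maximum linkable displacement in pixels.
#' @param minTrackLength tracks spanning fewer frames are flagged (column
#'   `short`), not removed.
#' @return data.frame sorted by (`track_id`, `frame`) with columns `frame`,
#'   `label`, `track_id`, `centroid_row`, `centroid_col`, `short`.
#' @export
trackMovie <- function(seg, maxDisplacement = 8, minTrackLength = 1L) {
    regions <- if (is(seg, "SegmentedMovie")) regionTable(seg) else seg
    if (!nrow(regions))
        return(data.frame(frame = integer(), label = integer(),
                          track_id = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), short = logical()))
    frames <- sort(unique(regions$frame))
    byFrame <- split(regions, regions$frame)
    nextId <- 1L
    rows <- vector("list", length(frames))
    prev <- NULL    # data.frame label,row,col,track_id of previous frame
    for (fi in seq_along(frames)) {
        cur <- byFrame[[as.character(frames[fi])]]
        cur <- cur[order(cur$label), ]
        curC <- data.frame(label = cur$label, row = cur$centroid_row,
                           col = cur$centroid_col)
        ids <- integer(nrow(cur))
        if (!is.null(prev) && frames[fi] == prev$frame[1L] + 1L) {
            m <- linkFrames(prev[, c("label", "row", "col")], curC,
                            maxDisplacement)
            if (nrow(m)) {
                mi <- match(m$curr_label, curC$label)
                ids[mi] <- prev$track_id[match(m$prev_label, prev$label)]
            }
        }
        for (i in which(ids == 0L)) {
            ids[i] <- nextId
            nextId <- nextId + 1L
        }
        rows[[fi]] <- data.frame(frame = frames[fi], label = curC$label,
                                 track_id = ids, centroid_row = curC$row,
                                 centroid_col = curC$col)
        prev <- data.frame(frame = frames[fi], label = curC$label,
                           row = curC$row, col = curC$col, track_id = ids)
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$track_id, tab$frame), ]
    len <- tapply(tab$frame, tab$track_id, length)
    tab$short <- len[as.character(tab$track_id)] < minTrackLength
    rownames(tab) <- NULL
    tab
}
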