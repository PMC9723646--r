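# Shared fixture builders and independent oracles used across test files.

# Small, fast scene for pipeline-level tests.
tinyScene <- function(nNuclei = 6L, frameCount = 20L, seed = 1L, ...) {
    demoScene(nNuclei = nNuclei, frameCount = frameCount,
              imageShape = c(3L, 112L, 112L), seed = seed, ...)
}

# Constructed bursty traces: rectangular ON episodes of >= `minOn` frames
# separated by >= `minGap` OFF frames, plateau `amp`, Gaussian noise at the
# requested SNR. Returns the measured trace and true 0-based ON intervals.
burstyTrace <- function(frames = 150L, amp = 100, snr = 10,
                        minOn = 8L, minGap = 10L) {
    v <- numeric(frames)
    iv <- NULL
    t <- sample(1:12, 1L)
    repeat {
        dur <- sample(minOn:(minOn + 8L), 1L)
        if (t + dur - 1L > frames - 2L) break
        v[t:(t + dur - 1L)] <- amp
        iv <- rbind(iv, c(t - 1L, t + dur - 2L))
        t <- t + dur + sample(minGap:(minGap + 15L), 1L)
    }
    noise <- if (snr > 0) rnorm(frames, 0, amp / snr) else 0
    list(trace = pmax(v + noise, 0), intervals = iv)
}

# Interval matching: a true interval is hit when some unused called
# interval overlaps it by >= 50% of the shorter interval's length.
matchIntervals <- function(truth, called) {
    if (is.null(truth)) truth <- matrix(numeric(), ncol = 2L)
    tp <- 0L
    used <- logical(NROW(called))
    for (k in seq_len(NROW(truth))) {
        s1 <- truth[k, 1L]; e1 <- truth[k, 2L]
        for (j in seq_len(NROW(called))) {
            if (used[j]) next
            ov <- min(e1, called[j, 2L]) - max(s1, called[j, 1L]) + 1
            if (ov >= 0.5 * min(e1 - s1 + 1,
                                called[j, 2L] - called[j, 1L] + 1)) {
                used[j] <- TRUE
                tp <- tp + 1L
                break
            }
        }
    }
    list(tp = tp, nTrue = NROW(truth), nCalled = NROW(called))
}

# Independent exhaustive-permutation rank-sum oracle (two-sided, midranks).
ranksumPermutationOracle <- function(a, b) {
    r <- rank(c(a, b))
    n1 <- length(a); N <- n1 + length(b)
    m <- min(n1, N - n1)
    sums <- combn(N, m, function(ix) sum(r[ix]))
    obs <- if (n1 <= N - n1) sum(r[seq_len(n1)]) else
        sum(r) - sum(r[seq_len(n1)])
    min(1, 2 * min(mean(sums <= obs + 1e-9), mean(sums >= obs - 1e-9)))
}

# Exhaustive optimal one-to-one assignment (minimum total distance among
# maximum-cardinality gated matchings), for <= 8 nuclei per side.
optimalAssignmentOracle <- function(prev, curr, maxDisp) {
    d <- sqrt(outer(prev$row, curr$row, `-`)^2 +
              outer(prev$col, curr$col, `-`)^2)
    np <- nrow(prev); nc <- nrow(curr)
    best <- NULL
    # enumerate injective maps from prev indices to curr indices (0 = none)
    rec <- function(i, usedC, pairs, total) {
        if (i > np) {
            card <- nrow(pairs)
            if (is.null(best) || card > nrow(best$pairs) ||
                (card == nrow(best$pairs) && total < best$total - 1e-12))
                best <<- list(pairs = pairs, total = total)
            return(invisible())
        }
        rec(i + 1L, usedC, pairs, total)     # leave i unmatched
        for (j in seq_len(nc)) {
            if (usedC[j] || d[i, j] > maxDisp) next
            u <- usedC; u[j] <- TRUE
            rec(i + 1L, u, rbind(pairs, c(i, j)), total + d[i, j])
        }
    }
    rec(1L, logical(nc), matrix(integer(), ncol = 2L), 0)
    best$pairs
}

# Map each detected track to the ground-truth nucleus nearest its
# detections, frame by frame; returns the fraction of (track, frame)
# records whose truth label equals the track's modal truth label.
trackIdentityAgreement <- function(tracks, truthCentroids, cropBox) {
    agree <- 0L; total <- 0L
    for (tid in unique(tracks$track_id)) {
        tt <- tracks[tracks$track_id == tid, ]
        labs <- integer(nrow(tt))
        for (i in seq_len(nrow(tt))) {
            tf <- truthCentroids[truthCentroids$frame == tt$frame[i], ]
            d <- sqrt((tf$row - cropBox[1L] - tt$centroid_row[i])^2 +
                      (tf$col - cropBox[2L] - tt$centroid_col[i])^2)
            labs[i] <- tf$label[which.min(d)]
        }
        modal <- as.integer(names(which.max(table(labs))))
        agree <- agree + sum(labs == modal)
        total <- total + length(labs)
    }
    agree / total
}

# Per-frame detection recall/precision against true centroids (1-1 match
# within `tol` px, greedy by distance).
frameRecallPrecision <- function(regions, truthCentroids, cropBox,
                                 tol = 3) {
    frames <- sort(unique(truthCentroids$frame))
    recall <- precision <- numeric(length(frames))
    for (fi in seq_along(frames)) {
        f <- frames[fi]
        tf <- truthCentroids[truthCentroids$frame == f, ]
        rf <- regions[regions$frame == f, ]
        if (!nrow(rf)) { recall[fi] <- 0; precision[fi] <- 1; next }
        d <- sqrt(outer(tf$row - cropBox[1L], rf$centroid_row, `-`)^2 +
                  outer(tf$col - cropBox[2L], rf$centroid_col, `-`)^2)
        usedT <- logical(nrow(tf)); usedR <- logical(nrow(rf))
        cand <- which(d <= tol, arr.ind = TRUE)
        cand <- cand[order(d[cand]), , drop = FALSE]
        tp <- 0L
        for (i in seq_len(nrow(cand))) {
            a <- cand[i, 1L]; b <- cand[i, 2L]
            if (usedT[a] || usedR[b]) next
            usedT[a] <- TRUE; usedR[b] <- TRUE
            tp <- tp + 1L
        }
        recall[fi] <- tp / nrow(tf)
        precision[fi] <- tp / nrow(rf)
    }
    list(recall = recall, precision = precision)
}
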