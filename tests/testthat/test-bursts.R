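test_that("moving-average smoothing matches the per-frame oracle", {
    expect_equal(smoothTrace(rep(7, 10), 5), rep(7, 10))

    imp <- numeric(11); imp[6] <- 1
    sm <- smoothTrace(imp, 5)
    expect_equal(sm[4:8], rep(0.2, 5))
    expect_equal(sm[1:3], c(0, 0, 0))

    set.seed(6)
    v <- rnorm(40)
    sm2 <- smoothTrace(v, 5)
    oracle <- vapply(seq_along(v), function(i) {
        lo <- max(1, i - 2); hi <- min(40, i + 2)
        mean(v[lo:hi])
    }, numeric(1))
    expect_equal(sm2, oracle)

    expect_error(smoothTrace(1:3, 5), "exceeds")
    expect_error(smoothTrace(1:10, 4), "odd")
})

test_that("a rectangular pulse is called as one shifted burst", {
    # pulse of height 10 on frames 20..39 (0-based), threshold 2:
    # smoothing ramps make frame 19 the first > 2, frame 40 the first
    # < 0.55 * 10, so the pre-shift call is [19, 39] and +2 gives [21, 41]
    v <- numeric(60); v[21:40] <- 10
    cfg <- BurstCallConfig(startThreshold = 2)
    b <- detectBursts(smoothTrace(v, 5), cfg)
    expect_identical(nrow(b), 1L)
    expect_identical(b$start_frame, 21L)
    expect_identical(b$end_frame, 41L)
    expect_identical(b$duration_frames, 21L)
    expect_equal(b$amplitude, 10)
    expect_equal(b$local_peak, 10)
    expect_gte(b$duration_frames, cfg@minDuration)
})

test_that("short above-threshold excursions are rejected as noise", {
    # 3 frames above threshold after smoothing -> candidate shorter than
    # 5 frames -> false positive
    v <- numeric(40); v[16:18] <- 4
    b <- detectBursts(smoothTrace(v, 5),
                      BurstCallConfig(startThreshold = 2))
    expect_identical(nrow(b), 0L)
})

test_that("a trace opening on a monotone decline is not a burst", {
    v <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, rep(0, 20))
    b <- detectBursts(smoothTrace(v, 5),
                      BurstCallConfig(startThreshold = 2))
    expect_identical(nrow(b), 0L)
})

test_that("an all-zero trace yields no bursts", {
    b <- detectBursts(rep(0, 50), BurstCallConfig(startThreshold = 2))
    expect_identical(nrow(b), 0L)
})

test_that("burst calls are scale-equivariant and deterministic", {
    set.seed(7)
    for (rep in 1:10) {
        tr <- burstyTrace(frames = 120L)
        sm <- smoothTrace(tr$trace - min(tr$trace), 5)
        cfg <- BurstCallConfig(startThreshold = 30)
        b1 <- detectBursts(sm, cfg)
        b2 <- detectBursts(sm, cfg)
        expect_identical(b1, b2)
        for (c_ in c(0.25, 3)) {
            bS <- detectBursts(sm * c_,
                               BurstCallConfig(startThreshold = 30 * c_))
            expect_identical(bS[, c("start_frame", "end_frame")],
                             b1[, c("start_frame", "end_frame")])
        }
        # invariants: ordering, non-overlap, min duration, peak above gate
        if (nrow(b1) > 1L)
            expect_true(all(b1$start_frame[-1] > b1$end_frame[-nrow(b1)]))
        expect_true(all(b1$duration_frames >= 5L))
        expect_true(all(b1$local_peak > 30))
    }
})

test_that("well-separated simulated bursts are recovered accurately", {
    set.seed(8)
    cfg <- BurstCallConfig(startThreshold = 30)
    tp <- 0L; nTrue <- 0L; nCalled <- 0L
    for (i in 1:50) {
        tr <- burstyTrace(frames = 150L, amp = 100, snr = 10)
        b <- detectBursts(smoothTrace(tr$trace - min(tr$trace), 5), cfg)
        m <- matchIntervals(tr$intervals,
                            as.matrix(b[, c("start_frame", "end_frame")]))
        tp <- tp + m$tp; nTrue <- nTrue + m$nTrue
        nCalled <- nCalled + m$nCalled
    }
    expect_gte(tp / nTrue, 0.9)
    expect_gte(tp / nCalled, 0.9)
})

test_that("burst properties summarize count, amplitude, duration, output", {
    v <- numeric(60); v[21:40] <- 10
    sm <- smoothTrace(v, 5)
    cfg <- BurstCallConfig(startThreshold = 2)
    b <- detectBursts(sm, cfg)
    props <- burstProperties(v, sm, b, frameInterval = 16.8)
    expect_identical(props$n_bursts, 1L)
    expect_equal(props$total_output, 200)       # 10 x 20 frames
    expect_equal(props$mean_amplitude, 10)
    expect_equal(props$mean_duration_s, props$mean_duration_frames * 16.8)

    none <- burstProperties(v, sm, b[0, ], 16.8)
    expect_identical(none$n_bursts, 0L)
    expect_equal(none$total_output, sum(v))
    expect_true(is.na(none$mean_amplitude))
})

test_that("called burst frequency rises with the ON-switching rate", {
    base <- TelegraphParams()
    ks <- c(0.5, 1, 2) * base@kOn
    kVal <- numeric(); nB <- integer()
    for (ki in seq_along(ks)) {
        p <- TelegraphParams(kOn = ks[ki], kOff = base@kOff,
                             loadingRate = base@loadingRate,
                             dwellTime = base@dwellTime)
        sim <- simulateTraceSet(p, 70, 150, 16.8, noiseSd = 20,
                                seed = 100L + ki)
        s <- summarizeBursts(sim$traces,
                             BurstCallConfig(startThreshold = 150))
        kVal <- c(kVal, rep(ks[ki], nrow(s$summary)))
        nB <- c(nB, s$summary$n_bursts)
    }
    ct <- suppressWarnings(cor.test(kVal, nB, method = "spearman"))
    expect_gt(ct$estimate, 0)
    expect_lt(ct$p.value, 0.01)
})

test_that("missing stretches split traces into independent segments", {
    v <- c(rep(0, 5), rep(10, 10), rep(0, 5), NA, NA,
           rep(0, 4), rep(10, 10), rep(0, 6))
    sm <- ms2burst:::smoothSegments(v, 5)
    b <- detectBursts(sm, BurstCallConfig(startThreshold = 2))
    expect_identical(nrow(b), 2L)
    # no call may span the missing gap
    expect_true(all(b$end_frame < 20 | b$start_frame > 21))
})

test_that("the data-derived threshold scales with the control signal", {
    set.seed(9)
    v <- pmax(rnorm(5000, 0, 10), 0)
    thr <- defaultStartThreshold(v)
    expect_equal(thr, 0.10 * quantile(v, 0.99, names = FALSE))
    expect_equal(defaultStartThreshold(v * 7), thr * 7)
    expect_error(defaultStartThreshold(NA_real_), "no values")
})
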