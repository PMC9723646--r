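test_that("the exact two-sided rank-sum p matches known small cases", {
    out <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
    expect_equal(out$p_value, 0.1)     # most extreme of C(6,3), doubled
    expect_identical(out$method, "exact")
    expect_equal(out$statistic, 6)

    expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
    expect_equal(wilcoxonRankSum(rep(5, 4), rep(5, 6))$p_value, 1)
    expect_error(wilcoxonRankSum(numeric(), 1:3), "non-empty")
})

test_that("exact p equals the exhaustive permutation oracle (min n <= 8)", {
    set.seed(10)
    for (i in 1:60) {
        n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
        withTies <- i %% 2 == 0
        a <- if (withTies) sample(0:5, n1, TRUE) else rnorm(n1)
        b <- if (withTies) sample(0:5, n2, TRUE) else rnorm(n2)
        out <- wilcoxonRankSum(a, b)
        expect_identical(out$method, "exact")
        expect_equal(out$p_value, ranksumPermutationOracle(a, b),
                     tolerance = 1e-12)
    }
    # untied exact p also agrees with the classical distribution
    set.seed(11)
    a <- rnorm(6); b <- rnorm(7) + 1
    expect_equal(wilcoxonRankSum(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
})

test_that("normal approximation stays within 0.02 of exact for n 8..12", {
    set.seed(12)
    for (i in 1:60) {
        n <- sample(8:12, 1)
        a <- rnorm(n); b <- rnorm(n, sample(c(0, 0.5, 1.5), 1))
        pe <- wilcoxonRankSum(a, b, exactMax = 12L)$p_value
        pn <- wilcoxonRankSum(a, b, exactMax = 0L)$p_value
        expect_lt(abs(pe - pn), 0.02)
    }
})

makeSummary <- function(cond, total, amp = NULL, dur = NULL, nb = NULL) {
    n <- length(total)
    data.frame(condition = cond, track_id = seq_len(n),
               n_bursts = if (is.null(nb)) rep(1L, n) else nb,
               mean_amplitude = if (is.null(amp)) total / 10 else amp,
               mean_duration_frames = 5,
               mean_duration_s = if (is.null(dur)) rep(84, n) else dur,
               total_output = total)
}

test_that("condition comparison reports medians, ratios and tests", {
    set.seed(13)
    s <- rbind(makeSummary("ctrl", rlnorm(60, 8)),
               makeSummary("kd", rlnorm(60, 8) * 0.4))
    cmp <- compareConditions(s, "ctrl")
    to <- cmp[cmp$metric == "total_output", ]
    expect_equal(to$median_ratio[to$condition == "ctrl"], 1)
    expect_equal(to$p_value[to$condition == "ctrl"], 1)
    expect_lt(to$median_ratio[to$condition == "kd"], 1)
    expect_lt(to$p_value[to$condition == "kd"], 0.01)
    expect_setequal(unique(cmp$metric),
                    c("total_output", "amplitude", "duration", "n_bursts"))
})

test_that("zero-burst nuclei enter output/frequency but not amplitude", {
    s <- rbind(makeSummary("ctrl", c(10, 20, 30, 40)),
               makeSummary("kd", c(1, 2, 3, 4)))
    s$mean_amplitude[s$condition == "kd"][1:2] <- NA
    s$mean_duration_s[s$condition == "kd"][1:2] <- NA
    s$n_bursts[s$condition == "kd"][1:2] <- 0L
    cmp <- compareConditions(s, "ctrl")
    expect_identical(cmp$n[cmp$metric == "total_output" &
                           cmp$condition == "kd"], 4L)
    expect_identical(cmp$n[cmp$metric == "n_bursts" &
                           cmp$condition == "kd"], 4L)
    expect_identical(cmp$n[cmp$metric == "amplitude" &
                           cmp$condition == "kd"], 2L)
})

test_that("comparisons are equivariant under a common scale factor", {
    set.seed(14)
    s1 <- rbind(makeSummary("ctrl", rlnorm(30, 5)),
                makeSummary("kd", rlnorm(30, 5) * 0.6))
    s2 <- s1
    for (col in c("total_output", "mean_amplitude", "mean_duration_s"))
        s2[[col]] <- s2[[col]] * 37
    c1 <- compareConditions(s1, "ctrl")
    c2 <- compareConditions(s2, "ctrl")
    expect_equal(c1$median_ratio, c2$median_ratio)
    expect_equal(c1$p_value, c2$p_value)
})

test_that("null comparisons reject at close to the nominal level", {
    set.seed(15)
    rej <- 0L; nRep <- 400L
    for (r in seq_len(nRep)) {
        p <- wilcoxonRankSum(rnorm(30), rnorm(30))$p_value
        rej <- rej + (p < 0.05)
    }
    expect_gte(rej / nRep, 0.02)
    expect_lte(rej / nRep, 0.08)
})

test_that("missing control or empty conditions are explicit errors", {
    s <- makeSummary("a", 1:10)
    expect_error(compareConditions(s, "ctrl"), "control")
    expect_error(compareConditions(s, "a"), "two conditions")
})

test_that("the report writes deterministic tables and figures", {
    set.seed(16)
    mkTs <- function(seed) {
        sim <- simulateTraceSet(TelegraphParams(), 12, 60, 16.8,
                                noiseSd = 20, seed = seed)
        sim$traces
    }
    tsA <- mkTs(1L); tsB <- mkTs(2L)
    sA <- summarizeBursts(tsA, BurstCallConfig(startThreshold = 150))
    sB <- summarizeBursts(tsB, BurstCallConfig(startThreshold = 150))
    summaries <- rbind(cbind(condition = "ctrl", sA$summary),
                       cbind(condition = "kd", sB$summary))
    cmp <- compareConditions(summaries, "ctrl")
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    cfg <- BurstCallConfig(startThreshold = 150)
    renderReport(cmp, list(ctrl = tsA, kd = tsB), summaries, d1, cfg)
    renderReport(cmp, list(ctrl = tsA, kd = tsB), summaries, d2, cfg)
    for (f in c("comparisons.tsv", "trajectory_heatmap.tsv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    expect_true(file.exists(file.path(d1, "trajectories.pdf")))
    heat <- readTable(file.path(d1, "trajectory_heatmap.tsv"))
    expect_identical(length(unique(heat$row[heat$condition == "ctrl"])),
                     12L)
    # earliest-onset nucleus occupies row 1
    h1 <- heat[heat$condition == "ctrl", ]
    onset <- tapply(seq_len(nrow(h1)), h1$row, function(ix) {
        sm <- smoothTrace(h1$value[ix], 5)
        w <- which(sm > 150)
        if (length(w)) w[1] else Inf
    })
    expect_identical(unname(which.min(onset)), 1L)
})
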