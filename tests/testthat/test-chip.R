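library(GenomicRanges)
library(IRanges)
library(S4Vectors)

uniformCov <- function(len, d = 2) {
    methods::as(IRanges::RleList(chr1 = S4Vectors::Rle(d, len)),
                "SimpleRleList")
}

covFromVector <- function(v, name = "chr1") {
    l <- IRanges::RleList(S4Vectors::Rle(v))
    names(l) <- name
    l
}

test_that("uniform coverage over a 3 kb gene gives a pausing index of 0.25", {
    cov <- uniformCov(10000, d = 2)
    gene <- GRanges("chr1", IRanges(4001, 7000), strand = "+")
    names(gene) <- "g1"
    rec <- pausingIndex(cov, gene)
    expect_equal(rec$promoter_signal, 500 * 2)
    expect_equal(rec$body_signal, 2000 * 2)
    expect_equal(rec$pausing_index, 0.25)
})

test_that("genes shorter than 1500 bp are removed", {
    cov <- uniformCov(10000)
    genes <- GRanges("chr1", IRanges(c(2001, 5001), width = c(1400, 1600)),
                     strand = "+")
    names(genes) <- c("short", "long")
    rec <- pausingIndex(cov, genes)
    expect_identical(rec$gene_id, "long")
})

test_that("minus-strand windows flip: an upstream spike lands in the promoter", {
    v <- rep(1, 10000)
    v[5100] <- 1001       # 100 bp upstream of the - strand TSS (gene end)
    cov <- covFromVector(v)
    gene <- GRanges("chr1", IRanges(2001, 5000), strand = "-")
    names(gene) <- "gm"
    rec <- pausingIndex(cov, gene)
    # promoter covers 1-based [4752, 5250]: 500 bases + spike excess
    expect_equal(rec$promoter_signal, 500 + 1000)
    # body covers [2501, 4500]
    expect_equal(rec$body_signal, 2000)
})

test_that("pausing index equals a per-base brute-force oracle", {
    set.seed(17)
    v <- rpois(50000, 2) * runif(50000)
    cov <- covFromVector(v)
    starts <- seq(2000, 45000, by = 4000)
    genes <- GRanges("chr1",
                     IRanges(starts, width = sample(1600:3500,
                                                    length(starts))),
                     strand = sample(c("+", "-"), length(starts), TRUE))
    names(genes) <- paste0("g", seq_along(genes))
    rec <- pausingIndex(cov, genes)
    for (i in seq_along(genes)) {
        s <- start(genes)[i]; e <- end(genes)[i]
        if (as.character(strand(genes))[i] == "+") {
            prom <- sum(v[(s - 250):(s + 249)])
        } else {
            prom <- sum(v[(e - 249):(e + 250)])
        }
        body <- sum(v[(s + 500):(e - 500)])
        expect_equal(rec$promoter_signal[i], prom)
        expect_equal(rec$body_signal[i], body)
        expect_equal(rec$pausing_index[i], prom / body)
    }
})

test_that("pausing indices are invariant under coordinate mirroring", {
    set.seed(18)
    L <- 20000L
    v <- rpois(L, 3)
    cov <- covFromVector(v)
    covFlip <- covFromVector(rev(v))
    genes <- GRanges("chr1", IRanges(c(3001, 9001), width = c(2000, 3000)),
                     strand = c("+", "-"))
    names(genes) <- c("a", "b")
    flipped <- GRanges("chr1",
                       IRanges(L - end(genes) + 1L, L - start(genes) + 1L),
                       strand = ifelse(strand(genes) == "+", "-", "+"))
    names(flipped) <- names(genes)
    expect_equal(pausingIndex(cov, genes)$pausing_index,
                 pausingIndex(covFlip, flipped)$pausing_index)
})

test_that("degenerate pausing inputs are handled explicitly", {
    cov <- uniformCov(1000)
    gene <- GRanges("chr1", IRanges(1, 2000), strand = "+")
    names(gene) <- "beyond"
    expect_error(pausingIndex(cov, gene), "beyond")

    zeroBody <- covFromVector(c(rep(5, 300), rep(0, 9700)))
    g2 <- GRanges("chr1", IRanges(4001, 7000), strand = "+")
    names(g2) <- "silent"
    expect_true(is.na(pausingIndex(zeroBody, g2)$pausing_index))
})

test_that("pausing CDFs compare distributions on a shared grid", {
    set.seed(19)
    a <- rlnorm(300)
    same <- pausingCdf(a, a)
    expect_equal(same$p_value, 1)
    expect_equal(same$table$cdf_a, same$table$cdf_b)

    # doubling shifts the CDF by log 2: F_b(2x) = F_a(x)
    out <- pausingCdf(a, 2 * a)
    expect_equal(stats::ecdf(2 * a)(2 * sort(a)),
                 stats::ecdf(a)(sort(a)))
    expect_lt(out$p_value, 0.01)

    paused <- c(rlnorm(400), rlnorm(100) * 5)
    expect_lt(pausingCdf(rlnorm(500), paused)$p_value, 0.01)
})

test_that("peak classification applies the RPM gate and log2 cutoff", {
    vA <- rep(0, 6000); vB <- rep(0, 6000)
    put <- function(v, at, h) { v[at:(at + 99)] <- h; v }
    vA <- put(vA, 1000, 10);  vB <- put(vB, 1000, 10)    # unchanged
    vA <- put(vA, 2000, 4.9); vB <- put(vB, 2000, 4)     # below gate
    vA <- put(vA, 3000, 8);   vB <- put(vB, 3000, 6)     # diminished
    vA <- put(vA, 4000, 20);  vB <- put(vB, 4000, 30)    # increased
    vA <- put(vA, 5000, 6);   vB <- put(vB, 5000, 5.94)  # -0.014, kept
    covA <- covFromVector(vA); covB <- covFromVector(vB)
    peaks <- GRanges("chr1", IRanges(c(950, 1950, 2950, 3950, 4950),
                                     width = 200))
    rec <- peakFoldChange(covA, covB, peaks)
    expect_identical(rec$filtered, c(FALSE, TRUE, FALSE, FALSE, FALSE))
    expect_equal(rec$log2_fc[1], 0)
    expect_identical(rec$class[1], "associated")
    expect_equal(rec$log2_fc[3], log2(0.75))
    expect_identical(rec$class[3], "diminished")
    expect_identical(rec$class[4], "associated")
    expect_identical(rec$class[5], "associated")
    # partition: every unfiltered peak has exactly one class
    expect_true(all(!is.na(rec$class[!rec$filtered])))
    expect_true(all(is.na(rec$class[rec$filtered])))
})

test_that("diminished calls recover scaled-down peaks exactly when noise-free", {
    set.seed(20)
    L <- 40000L
    v <- rep(0, L)
    starts <- seq(1000, 38000, by = 2000)
    hit <- seq_along(starts) %% 3 == 0
    for (i in seq_along(starts))
        v[starts[i]:(starts[i] + 199)] <- runif(1, 6, 50)
    vB <- v
    for (i in which(hit))
        vB[starts[i]:(starts[i] + 199)] <-
            v[starts[i]:(starts[i] + 199)] * 0.7
    rec <- peakFoldChange(covFromVector(v), covFromVector(vB),
                          GRanges("chr1", IRanges(starts, width = 200)))
    expect_identical(rec$class == "diminished", hit)
})

test_that("RPM scaling divides by library size in millions", {
    cov <- uniformCov(100, d = 3)
    out <- rpmScale(cov, mappedReads = 2e6)
    expect_equal(as.numeric(out$chr1[1]), 1.5)
    expect_error(rpmScale(cov, 0), "mappedReads")
})
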