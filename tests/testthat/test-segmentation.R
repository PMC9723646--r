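test_that("max projection equals the per-pixel maximum over z", {
    one <- array(runif(64), c(1, 8, 8))
    expect_equal(maxProject(one), one[1, , ])

    a <- array(0, c(2, 4, 4)); a[1, 1, 1] <- 5; a[2, 3, 2] <- 7
    m <- maxProject(a)
    expect_equal(m[1, 1], 5)
    expect_equal(m[3, 2], 7)

    set.seed(1)
    stack <- array(rnorm(26 * 64 * 64), c(26, 64, 64))
    oracle <- matrix(0, 64, 64)
    for (i in 1:64) for (j in 1:64) oracle[i, j] <- max(stack[, i, j])
    expect_equal(maxProject(stack), oracle)

    expect_error(maxProject(array(0, c(0, 4, 4))), "plane")
})

test_that("cropping is exact, 0-based and half-open", {
    img <- matrix(runif(512 * 512), 512, 512)
    expect_equal(cropFrame(img, c(0, 0, 512, 512)), img)
    cropped <- cropFrame(img, c(106, 41, 300, 430))
    expect_identical(dim(cropped), c(300L, 430L))
    expect_equal(cropped[1, 1], img[107, 42])
    expect_equal(cropFrame(img, c(10, 20, 1, 1))[1, 1], img[11, 21])
    expect_error(cropFrame(img, c(400, 400, 200, 200)), "out of bounds")
})

test_that("preprocessing clips the bright tail to the quantile value", {
    img <- matrix(100, 20, 20)
    expect_equal(preprocessNuclei(img, blurSigma = 0,
                                  brightTailFraction = 0), img)
    expect_equal(preprocessNuclei(img, blurSigma = 2,
                                  brightTailFraction = 0.05), img)

    set.seed(2)
    img2 <- matrix(runif(400, 0, 100), 20, 20)
    img2[7, 7] <- 1e5
    out <- preprocessNuclei(img2, blurSigma = 0, brightTailFraction = 0.05)
    cutoff <- sort(as.vector(img2))[ceiling(0.95 * 400)]  # sorting oracle
    expect_lte(max(out), quantile(img2, 0.95) + 1e-9)
    expect_lt(abs(max(out) - cutoff), diff(range(img2[-which.max(img2)])))
    expect_equal(out[img2 <= quantile(img2, 0.95)],
                 img2[img2 <= quantile(img2, 0.95)])

    outMax <- preprocessNuclei(img2, blurSigma = 0,
                               brightTailFraction = 0.05,
                               mode = "max_fraction")
    expect_equal(max(outMax), 0.95 * max(img2))
})

test_that("adaptive threshold recovers the configured component count", {
    sc <- tinyScene(nNuclei = 8L, frameCount = 1L, noisePoissonGain = 0,
                    noiseReadSd = 0)
    out <- renderMovie(matrix(0, 8, 1), sc)
    proj <- maxProject(ms2burst:::frameStack(nucleiChannel(out$movie), 1L))
    pre <- preprocessNuclei(proj, 2, 0.05)
    at <- adaptiveThreshold(pre, expectedCount = c(6, 10),
                            sizeBounds = c(100, 400))
    expect_false(at$degraded)
    expect_identical(at$nComponents, 8L)

    blank <- adaptiveThreshold(matrix(0, 32, 32))
    expect_true(blank$degraded)
    expect_false(any(blank$mask))
})

test_that("threshold scanning splits touching intensity blobs", {
    # two Gaussian mounds whose union is connected at low thresholds
    g <- outer(1:40, 1:60, function(r, c)
        exp(-((r - 20)^2 + (c - 22)^2) / (2 * 5^2)) +
        exp(-((r - 20)^2 + (c - 38)^2) / (2 * 5^2)))
    low <- EBImage::bwlabel(g > quantile(g, 0.05))
    expect_identical(max(low), 1L)     # merged at a low threshold
    at <- adaptiveThreshold(g, expectedCount = c(2, 2),
                            sizeBounds = c(10, 400))
    expect_identical(at$nComponents, 2L)
    expect_false(at$degraded)
})

test_that("transcription dots are pixels above twice the frame mean", {
    expect_identical(nrow(detectMs2Dots(matrix(7, 16, 16))$centroids), 0L)

    img <- matrix(100, 32, 32)
    img[10:14, 20:24] <- 1000
    d <- detectMs2Dots(img)
    expect_identical(nrow(d$centroids), 1L)
    expect_equal(d$centroids$row, 11)   # 0-based centroid of rows 10..14
    expect_equal(d$centroids$col, 21)
    expect_identical(sum(d$mask), 25L)
})

test_that("stray dots are attached to the nucleus with the nearest boundary", {
    labels <- matrix(0L, 40, 40)
    labels[5:15, 5:15] <- 1L      # nucleus 1
    labels[25:35, 25:35] <- 2L    # nucleus 2

    inside <- data.frame(label = 1L, row = 9, col = 9)
    expect_identical(attachDots(labels, inside), labels)

    # 3 px outside nucleus 1's right edge (0-based col 17)
    outside <- data.frame(label = 1L, row = 9, col = 17)
    out <- attachDots(labels, outside)
    expect_identical(out[10, 18], 1L)
    expect_identical(sum(out == 2L), sum(labels == 2L))  # 2 untouched
    kept <- labels > 0L
    expect_identical(out[kept], labels[kept])            # disjointness

    expect_warning(attachDots(matrix(0L, 10, 10),
                              data.frame(label = 1L, row = 4, col = 4)),
                   "unassigned")
})

test_that("voronoi partition matches the exhaustive nearest-centroid oracle", {
    one <- voronoiPartition(data.frame(label = 3L, row = 5, col = 5),
                            c(16, 16))
    expect_true(all(one == 3L))

    two <- voronoiPartition(data.frame(label = 1:2, row = c(8, 8),
                                       col = c(4, 12)), c(17, 17))
    expect_true(all(two[, 1:8] == 1L))
    expect_true(all(two[, 9] == 1L))    # bisector column ties to label 1
    expect_true(all(two[, 10:17] == 2L))

    set.seed(3)
    cents <- data.frame(label = 1:20, row = runif(20, 0, 63),
                        col = runif(20, 0, 63))
    vp <- voronoiPartition(cents, c(64, 64))
    for (i in seq(1, 64, by = 3)) for (j in seq(1, 64, by = 3)) {
        d2 <- (cents$row - (i - 1))^2 + (cents$col - (j - 1))^2
        expect_identical(vp[i, j], cents$label[which.min(d2)])
    }
    expect_error(voronoiPartition(data.frame(label = integer(),
                                             row = numeric(),
                                             col = numeric()), c(8, 8)),
                 "centroid")
})

test_that("segmentation recovers every nucleus on a clean fixture", {
    sc <- tinyScene(nNuclei = 8L, frameCount = 6L, noisePoissonGain = 0,
                    noiseReadSd = 0, seed = 5L)
    sim <- simulateScene(sc)
    seg <- segmentMovie(sim$movie,
                        segmentationConfig(expectedCount = c(6, 10),
                                           sizeBounds = c(100, 400)))
    qc <- qcTable(seg)
    expect_true(all(qc$n_components == 8L))
    expect_false(any(qc$degraded))

    rp <- frameRecallPrecision(regionTable(seg), trueCentroids(sim$truth),
                               cropBox(seg), tol = 2)
    expect_true(all(rp$recall == 1))
    expect_true(all(rp$precision == 1))

    # structural invariants: positive labels, disjoint regions, dots inside
    for (f in seq_len(nFrames(seg))) {
        lab <- labelImages(seg)[[f]]
        expect_true(all(lab >= 0L))
        reg <- regionTable(seg)
        reg <- reg[reg$frame == f - 1L, ]
        expect_identical(anyDuplicated(reg$label), 0L)
    }
})

test_that("a blank movie segments to empty, degraded frames", {
    blank <- MovieStack(ms2 = array(0, c(2, 2, 32, 32)),
                        nuclei = array(0, c(2, 2, 32, 32)))
    seg <- segmentMovie(blank)
    expect_true(all(qcTable(seg)$degraded))
    expect_identical(nrow(regionTable(seg)), 0L)
})

test_that("a drifting spot outside its nucleus mask is captured every frame", {
    # nucleus disk at a fixed spot; transcription dot rendered 10 px to the
    # right of the nucleus edge so the initial mask cannot contain it
    nf <- 4L
    nuc <- array(0, c(nf, 1, 64, 64))
    ms2 <- array(10, c(nf, 1, 64, 64))
    for (f in seq_len(nf)) {
        img <- matrix(0, 64, 64)
        img <- ms2burst:::addDisk(img, 30, 24, 8, 500)
        nuc[f, 1, , ] <- img + 20
        spot <- matrix(10, 64, 64)
        spot <- ms2burst:::addGaussianSpot(spot, 30, 24 + 8 + 3 + f, 1.5,
                                           1.5, 3000)
        ms2[f, 1, , ] <- spot
    }
    movie <- MovieStack(ms2 = ms2, nuclei = nuc)
    seg <- segmentMovie(movie,
                        segmentationConfig(expectedCount = c(1, 1),
                                           sizeBounds = c(100, 400)))
    for (f in seq_len(nf)) {
        lab <- labelImages(seg)[[f]]
        dotCol <- round(24 + 8 + 3 + f) + 1L
        expect_identical(lab[31, dotCol], 1L)
    }
})
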