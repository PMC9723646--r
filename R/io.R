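#' Read a two-channel movie from multi-page TIFF files
#'
#' Pages are expected frames-major: for a movie with `nz` z-sections, pages
#' `1..nz` are frame 1, pages `nz+1..2nz` frame 2, and so on (the layout
#' written by [writeMovie()] and by [makeFixture()]).
#'
#' @param ms2Path path to the transcription-channel TIFF.
#' @param nucleiPath path to the nuclei-channel TIFF.
#' @param nz number of z-sections per frame.
#' @param frameInterval,pixelSize,zStep acquisition metadata.
#' @return A [MovieStack].
#' @export
readMovie <- function(ms2Path, nucleiPath, nz, frameInterval = 16.8,
                      pixelSize = 0.2, zStep = 0.5) {
    readCh <- function(path) {
        pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
        if (!length(pages))
            stopf("no pages in TIFF file '%s'", path)
        if (length(pages) %% nz != 0L)
            stopf("'%s': %d pages not divisible by nz = %d", path,
                  length(pages), nz)
        nf <- length(pages) %/% nz
        d <- dim(pages[[1L]])
        arr <- array(0, c(nf, nz, d[1L], d[2L]))
        for (f in seq_len(nf))
            for (z in seq_len(nz)) {
                p <- pages[[(f - 1L) * nz + z]]
                if (!identical(dim(p), d))
                    stopf("'%s': page %d has inconsistent dimensions", path,
                          (f - 1L) * nz + z)
                arr[f, z, , ] <- p
            }
        arr
    }
    ms2 <- readCh(ms2Path)
    nuc <- readCh(nucleiPath)
    MovieStack(ms2 = ms2, nuclei = nuc, frameInterval = frameInterval,
               pixelSize = pixelSize, zStep = zStep)
}

#' Write a movie as one 16-bit multi-page TIFF per channel
#'
#' Intensities are rounded and clamped to the unsigned 16-bit range; page
#' order is frames-major (all z of frame 1, then frame 2, ...). Integer
#' data in `[0, 65535]` round-trips losslessly through [readMovie()].
#'
#' @param movie a [MovieStack].
#' @param ms2Path,nucleiPath output paths.
#' @return Invisibly, `movie`.
#' @export
writeMovie <- function(movie, ms2Path, nucleiPath) {
    stopifnot(is(movie, "MovieStack"))
    writeCh <- function(arr, path) {
        d <- dim(arr)
        pages <- vector("list", d[1L] * d[2L])
        k <- 1L
        for (f in seq_len(d[1L]))
            for (z in seq_len(d[2L])) {
                pages[[k]] <- pmin(pmax(round(arr[f, z, , ]), 0), 65535) / 65535
                k <- k + 1L
            }
        tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    }
    writeCh(movie@ms2, ms2Path)
    writeCh(movie@nuclei, nucleiPath)
    invisible(movie)
}

#' Read/write the canonical tab-separated table dialect
#'
#' Tables are TSV with a header row, UTF-8, `.` decimal separator, full
#' float precision; column order is preserved on round-trip.
#'
#' @param x a data.frame.
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return `writeTable` invisibly returns `x`; `readTable` returns a
#'   data.frame.
#' @export
writeTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(x)
}

#' @rdname writeTable
#' @export
readTable <- function(path, required = NULL) {
    if (!file.exists(path)) stopf("file not found: '%s'", path)
    x <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(required)) {
        miss <- setdiff(required, names(x))
        if (length(miss))
            stopf("'%s': missing required column(s): %s", path,
                  paste(miss, collapse = ", "))
    }
    x
}

#' Read a coverage track from a bedGraph file
#'
#' Imports a bedGraph (via `rtracklayer`) and expands it to per-base
#' run-length-encoded coverage, one `Rle` per chromosome.
#'
#' @param path bedGraph file path.
#' @param seqlengths optional named integer vector of chromosome lengths;
#'   defaults to the largest end coordinate seen per chromosome.
#' @return An [IRanges::RleList] of per-base coverage.
#' @export
readCoverageBedGraph <- function(path, seqlengths = NULL) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    GenomicRanges::coverage(gr, weight = "score")
}

#' @rdname readCoverageBedGraph
#' @param cov an `RleList` of per-base coverage.
#' @export
writeCoverageBedGraph <- function(cov, path) {
    gr <- GenomicRanges::bindAsGRanges(score = cov)
    gr <- gr[gr$score != 0]
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read gene or peak intervals from a BED file
#'
#' @param path BED (3-6 column) file path.
#' @return A [GenomicRanges::GRanges]; the BED name column (if present)
#'   becomes `names()`.
#' @export
readBedIntervals <- function(path) {
    rtracklayer::import(path, format = "BED")
}
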