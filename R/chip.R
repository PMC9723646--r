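#' @importFrom GenomicRanges GRanges seqnames start end width strand promoters
#' @importFrom IRanges IRanges Views viewSums viewMaxs
NULL

# Per-range aggregate of an RleList coverage: fun is viewSums or viewMaxs.
# Windows are clipped to [1, chromosome length]; empty windows give 0.
rangeAggregate <- function(cov, gr, fun) {
    out <- numeric(length(gr))
    chrs <- as.character(seqnames(gr))
    for (chr in unique(chrs)) {
        if (!(chr %in% names(cov)))
            stopf("chromosome '%s' absent from coverage track", chr)
        sel <- which(chrs == chr)
        len <- length(cov[[chr]])
        s <- pmax(start(gr)[sel], 1L)
        e <- pmin(end(gr)[sel], len)
        ok <- s <= e
        vals <- numeric(length(sel))
        if (any(ok))
            vals[ok] <- fun(Views(cov[[chr]], IRanges(s[ok], e[ok])))
        out[sel] <- vals
    }
    out
}

geneIds <- function(genes) {
    ids <- names(genes)
    if (is.null(ids) && !is.null(genes$name)) ids <- genes$name
    if (is.null(ids)) ids <- paste0("gene_", seq_along(genes))
    ids
}

#' Promoter-proximal RNA polymerase II pausing index
#'
#' For every gene of at least `minGeneLength` bp, sums per-base Pol II
#' coverage over the promoter-proximal window (TSS - 250 to TSS + 250,
#' 500 bp, oriented by strand) and the gene body (TSS + 500 to TES - 500)
#' and reports their ratio. Genes with zero body signal get an undefined
#' (`NA`) index and are excluded from distributional summaries.
#'
#' @param cov an `RleList` of per-base coverage (RPM-normalized), e.g. from
#'   [readCoverageBedGraph()].
#' @param genes a [GenomicRanges::GRanges] of gene bodies with strand
#'   (`+`/`-`); names (or a `name` column) identify genes.
#' @param minGeneLength genes shorter than this many bp are removed.
#' @return data.frame: `gene_id`, `chrom`, `length`, `promoter_signal`,
#'   `body_signal`, `pausing_index`.
#' @export
pausingIndex <- function(cov, genes, minGeneLength = 1500) {
    if (!length(genes))
        return(data.frame(gene_id = character(), chrom = character(),
                          length = integer(), promoter_signal = numeric(),
                          body_signal = numeric(),
                          pausing_index = numeric()))
    if (any(!as.character(strand(genes)) %in% c("+", "-")))
        stopf("all genes must have strand '+' or '-'")
    ids <- geneIds(genes)
    chrs <- as.character(seqnames(genes))
    for (i in seq_along(genes)) {
        if (!(chrs[i] %in% names(cov)))
            stopf("gene '%s': chromosome '%s' absent from coverage",
                  ids[i], chrs[i])
        if (start(genes)[i] < 1L ||
            end(genes)[i] > length(cov[[chrs[i]]]))
            stopf("gene '%s' extends beyond chromosome '%s'", ids[i],
                  chrs[i])
    }
    keep <- width(genes) >= minGeneLength
    genes <- genes[keep]
    ids <- ids[keep]
    if (!length(genes))
        return(data.frame(gene_id = character(), chrom = character(),
                          length = integer(), promoter_signal = numeric(),
                          body_signal = numeric(),
                          pausing_index = numeric()))
    prom <- promoters(genes, upstream = 250, downstream = 250)
    body <- GRanges(seqnames(genes),
                    IRanges(start(genes) + 500L, end(genes) - 500L),
                    strand = strand(genes))
    promSig <- rangeAggregate(cov, prom, viewSums)
    bodySig <- rangeAggregate(cov, body, viewSums)
    data.frame(gene_id = ids,
               chrom = as.character(seqnames(genes)),
               length = width(genes),
               promoter_signal = promSig,
               body_signal = bodySig,
               pausing_index = ifelse(bodySig > 0, promSig / bodySig,
                                      NA_real_))
}

#' Cumulative distributions of two pausing-index sets
#'
#' Empirical CDFs of two pausing-index collections evaluated on a shared
#' log-spaced grid, plus a two-sided Wilcoxon rank-sum test of the two
#' sets (undefined indices dropped).
#'
#' @param indexA,indexB numeric vectors of pausing indices (e.g. the
#'   `pausing_index` column of [pausingIndex()] for two gene sets).
#' @param gridLength number of grid points.
#' @return list: `table` (data.frame `index`, `cdf_a`, `cdf_b`),
#'   `p_value`, `statistic`.
#' @export
pausingCdf <- function(indexA, indexB, gridLength = 200L) {
    a <- indexA[is.finite(indexA) & indexA > 0]
    b <- indexB[is.finite(indexB) & indexB > 0]
    if (!length(a) || !length(b))
        stopf("both index sets must contain positive finite values")
    rng <- range(c(a, b))
    grid <- exp(seq(log(rng[1L]), log(rng[2L]), length.out = gridLength))
    tst <- wilcoxonRankSum(a, b)
    list(table = data.frame(index = grid,
                            cdf_a = stats::ecdf(a)(grid),
                            cdf_b = stats::ecdf(b)(grid)),
         p_value = tst$p_value, statistic = tst$statistic)
}

#' Per-peak maximum-coverage fold change between two conditions
#'
#' For every peak interval, takes the maximum per-base coverage in the
#' control and treatment tracks. Peaks whose control maximum is below
#' `minControlRpm` (or whose maximum is zero in either condition) are
#' filtered out; the rest are classified by `log2(max_treatment /
#' max_control)`: `"diminished"` below `diminishedCutoff`, otherwise
#' `"associated"`.
#'
#' @param covControl,covTreatment `RleList` coverage tracks (RPM).
#' @param peaks a [GenomicRanges::GRanges] of peak intervals.
#' @param minControlRpm minimum control maximum (RPM) to retain a peak.
#' @param diminishedCutoff log2 fold-change threshold for the
#'   `"diminished"` class.
#' @return data.frame: `chrom`, `start` (0-based), `end` (exclusive),
#'   `max_control`, `max_treatment`, `log2_fc`, `filtered`, `class`
#'   (`NA` for filtered peaks).
#' @export
peakFoldChange <- function(covControl, covTreatment, peaks,
                           minControlRpm = 5.0, diminishedCutoff = -0.1) {
    if (!length(peaks))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), max_control = numeric(),
                          max_treatment = numeric(), log2_fc = numeric(),
                          filtered = logical(), class = character()))
    maxA <- rangeAggregate(covControl, peaks, viewMaxs)
    maxB <- rangeAggregate(covTreatment, peaks, viewMaxs)
    filtered <- maxA < minControlRpm | maxA <= 0 | maxB <= 0
    lfc <- rep(NA_real_, length(peaks))
    lfc[!filtered] <- log2(maxB[!filtered] / maxA[!filtered])
    cls <- rep(NA_character_, length(peaks))
    cls[!filtered] <- ifelse(lfc[!filtered] < diminishedCutoff,
                             "diminished", "associated")
    data.frame(chrom = as.character(seqnames(peaks)),
               start = start(peaks) - 1L, end = end(peaks),
               max_control = maxA, max_treatment = maxB, log2_fc = lfc,
               filtered = filtered, class = cls)
}

#' Scale a raw-count coverage track to reads per million
#'
#' @param cov an `RleList` of raw per-base coverage.
#' @param mappedReads total mapped reads of the library.
#' @return The coverage scaled by `1e6 / mappedReads`.
#' @export
rpmScale <- function(cov, mappedReads) {
    if (mappedReads <= 0) stopf("'mappedReads' must be > 0")
    cov * (1e6 / mappedReads)
}
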