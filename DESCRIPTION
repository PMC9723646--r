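Package: ms2burst
Title: Quantification of Transcriptional Bursting from MS2/MCP Live-Imaging Movies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantitative analysis of nascent
    transcription in MS2/MCP live-imaging movies of early Drosophila embryos:
    nuclei segmentation from a histone-marker channel (adaptive thresholding
    with transcription-dot-aware boundary correction and Voronoi territories),
    nearest-centroid nucleus tracking, per-nucleus transcription-site
    quantification by local 2-D Gaussian fitting with background estimation,
    rule-based transcriptional burst calling on baseline-zeroed traces, and
    between-condition burst-property statistics (two-sided Wilcoxon rank-sum).
    Includes a synthetic two-channel movie generator driven by a two-state
    (telegraph) promoter model that emits full ground truth, so that every
    stage is testable without external data, and RNA polymerase II ChIP-seq
    derived metrics (promoter-proximal pausing index and per-peak maximum
    coverage fold-change classification) on standard BED/bedGraph inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    yaml,
    minpack.lm,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Transcription, Visualization, TimeCourse
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bursts.R'
    'chip.R'
    'io.R'
    'pipeline.R'
    'render.R'
    'segmentation.R'
    'spot.R'
    'stats.R'
    'telegraph.R'
    'tracking.R'
    'utils.R'
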