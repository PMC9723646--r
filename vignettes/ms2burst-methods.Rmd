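---
title: "Quantifying transcriptional bursts from MS2 live-imaging movies: models and methods"
author: "ms2burst authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional bursts from MS2 live-imaging movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ms2burst` turns two-channel time-lapse movies of blastoderm-stage
*Drosophila* embryos — a histone-marker channel labelling every nucleus
and an MCP–GFP channel in which nascent transcription appears as one
bright dot per active nucleus — into per-nucleus transcriptional burst
statistics, and compares those statistics between reporter conditions.
Because raw embryo movies are large and rarely deposited, the package
carries its own synthetic movie generator with complete ground truth;
every processing stage is validated against that ground truth rather than
against expert annotation. A separate module computes two RNA polymerase
II ChIP-seq summaries (promoter-proximal pausing index, per-peak maximum
coverage fold change) on standard BED/bedGraph inputs.

This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions taken where
the procedure was genuinely open — together with what the synthetic
benchmarks do and do not demonstrate about real data.

# The telegraph model and the synthetic movie generator

## Promoter model

Each nucleus's promoter is a two-state Markov chain: OFF → ON at rate
$k_{on}$ (1/s), ON → OFF at rate $k_{off}$. While ON, transcripts initiate
as a Poisson process with rate $\lambda$ (`loadingRate`). Each nascent
transcript contributes one unit of signal for a fixed residence
(`dwellTime`, $\tau$) — a boxcar, with no elongation ramp. The observable
at frame time $t$ is therefore the number of initiations in
$(t-\tau, t]$. The chain is simulated exactly in continuous time
(Gillespie), then sampled at frame boundaries, so there is no
time-discretization bias; the boxcar (rather than a trapezoid tracking
polymerase traversal) is the simplest signal model that produces
burst-shaped traces and can be replaced later without touching the
samplers. Two classical identities anchor the tests: the stationary ON
fraction is $k_{on}/(k_{on}+k_{off})$, and a permanently ON promoter is an
M/D/$\infty$ queue whose mean occupancy is $\lambda\tau$.

Default kinetics (`TelegraphParams()`): $k_{on} = 0.008$/s,
$k_{off} = 0.012$/s (ON fraction 0.4, mean ON episode ≈ 83 s ≈ 5 frames),
$\lambda = 0.2$/s, $\tau = 150$ s. These give ON episodes of a few frames,
tens of transcripts at steady state, and inter-burst gaps of minutes —
realistic orders of magnitude for a strong developmental enhancer driving
a reporter in nuclear cycle 14, chosen once as the package's study
conditions.

## Rendering

The default scene (`demoScene()`) renders 50 nuclei for 200 frames at
16.8 s/frame into a 3-z × 300 × 430 px stack: nuclei are uniform disks
(radius 8 px) with a soft 1-px edge; the transcription spot is an
elliptical Gaussian ($\sigma_y = \sigma_x = 2$ px) placed at the nucleus
centroid plus a small fixed offset, brightest at the middle z-plane with
Gaussian z-attenuation (1 plane s.d.); the spot channel has a flat
background (100 intensity units) and both channels get shot noise
(Poisson, gain 1) and Gaussian read noise (s.d. 3). One nascent
transcript contributes 40 intensity units of integrated spot signal on
the brightest plane, so the rendered background-subtracted integral
equals the true trace value exactly when noise is off (the conservation
property the tests check to < 1% discretization error). Three z-planes —
not the 26 of a real acquisition — keep a full study-scale movie around
half a gigabyte in memory; nothing downstream depends on the z count
beyond "the spot is brightest on one plane".

Nuclear cycle 14 has no divisions, so none are simulated; the slow drift
of the embryo is modelled as a *field-wide* reflected Gaussian random walk
(s.d. 0.5 px/frame) shared by all nuclei. A shared walk was chosen over
independent per-nucleus walks deliberately: it reproduces the dominant
motion mode of a mounted embryo (stage/tissue drift) and guarantees by
construction that nuclei never collide no matter how long the movie runs.
Initial positions come from a jittered grid with surface separation
≥ 4 px. All randomness flows from one master seed via fixed per-stream
offsets; fixtures written with the same seed are byte-identical.

What the generator does *not* emulate — photobleaching, chromatic shift,
3-D point-spread functions, mitotic figures, nuclear import gradients,
segmentation-adversarial clutter — bounds what the green benchmarks mean:
they demonstrate correctness of the algorithms under the stated optical
model, not robustness to every real-world artefact. On real movies the
manual-correction hook (`maskOverride`) and the per-frame QC log are the
intended safety valves.

# Segmentation

Per frame: maximum z-projection; crop (default: a centred 300 × 430 box
on 512 × 512 inputs, to discard edge nuclei; full frame otherwise; always
configurable); Gaussian blur ($\sigma = 2$ px); bright-tail suppression;
adaptive thresholding; connected-component labelling with a small-object
filter (< 20 px discarded, debris control); dot-aware boundary
correction; Voronoi partition. Coordinates are 0-based (row, col) with
half-open crop boxes throughout the tables.

Two points in the recipe were underdetermined and are declared decisions:

* **Bright-tail suppression.** "Remove the brightest few percent of
  pixels" admits two readings. The default clips the brightest 5% of
  pixels to the 95th-percentile value (quantile clipping) — removal by
  zeroing would punch holes into nuclei and split components. The
  alternative reading (clip values above 95% of the global maximum) is
  available as `mode = "max_fraction"`.
* **Adaptive threshold search.** Candidate thresholds are the 5th–95th
  percentiles of the preprocessed frame in 1-percentile steps; each
  candidate is scored by two indicators — connected-component count
  within the expected range, median component area within the size
  bounds — and ties are broken toward the candidate nearest Otsu's
  threshold. If no candidate scores 2 the best one is used and the frame
  is flagged `degraded` in the QC table. This scanner is a concrete,
  reproducible stand-in for an unspecified per-frame heuristic; its two
  ranges are the only segmentation parameters that need per-dataset
  attention.

The MS2 channel projection is thresholded at twice its mean to find
transcription dots; a dot whose centroid falls outside all nucleus masks
is captured by the nucleus whose *boundary pixel* is nearest (Euclidean;
ties to the lower label), dilating the mask along the straight path to
the dot. Only background pixels are rewritten, so masks stay disjoint.
Finally the nucleus centroids define a Voronoi partition (ties to the
lower label) that serves as each nucleus's measurement territory: the
spot search downstream runs over the territory, not the mask, so a spot
just outside the chromatin mask still belongs to its nucleus. Interactive
mask editing has no place in an automated pipeline; a per-frame label
override (`maskOverride`) replaces it.

# Tracking

Frame-to-frame linking is greedy in ascending centroid distance with a
hard displacement gate (default 8 px = the nucleus radius; there is no
natural gate in a pure minimum-distance rule, so the radius is used),
one-to-one by construction, ties broken toward the lower previous-frame
label. Unmatched current nuclei start new tracks; unmatched previous
nuclei terminate — there is no gap closing, so a missed detection ends a
track rather than inventing an interpolated nucleus. One-to-one matching
(rather than per-nucleus independent minima, which can merge lineages)
was chosen because lineage identity is the quantity downstream statistics
depend on. For blastoderm-like motion — per-frame displacement far below
half the inter-nucleus spacing — greedy linking coincides with the
exhaustive optimal assignment; the tests verify this on enumerable
instances (≤ 8 nuclei) and verify 100% identity agreement on drifting
synthetic movies.

# Spot quantification

For each track and frame, the brightest voxel over the territory × all
z-planes picks the fit site (ties to the lowest z, row, col); an 11 × 11
window on that single z-plane is fit by ordinary (unweighted) nonlinear
least squares to

$$I(x,y) \;=\; \alpha + I_0\,
  \exp\!\Big(\!-\Big(\tfrac{(x-x_0)^2}{2\sigma_x^2}
  + \tfrac{(y-y_0)^2}{2\sigma_y^2}\Big)\Big),$$

and the background-subtracted spot intensity is the analytic integral
$2\pi\sigma_x\sigma_y I_0$ — an identity the code enforces exactly.
Initialization is robust and standard: $\alpha$ = window median,
$I_0$ = max − median, centre of window, $\sigma = 1.5$ px.
Levenberg–Marquardt with box constraints does the optimization. The
acceptance gates are the package's own (none are inherited):
convergence, $I_0 > 0$, $0.3 \le \sigma_x,\sigma_y \le 6$ px (a spot
narrower than a pixel or wider than the window is not a diffraction-
limited spot), centre inside the window, and a non-constant window.
Windows truncated by the image edge are fit if at least 7 × 7 pixels
remain, and flagged. A failed fit contributes integral 0 — after
baseline-zeroing this reproduces the zero-floor behaviour of inactive
nuclei — whereas a frame where the track is absent is *missing* (`NA`),
excluded from the baseline and from burst calling.

Each assembled trajectory is baseline-zeroed by subtracting its minimum
over valid frames, making traces comparable across nuclei with different
residual backgrounds.

# Burst calling

On the 5-frame moving-average smoothed trace (centred window, shrinking
at the edges), a state machine opens a burst at the first frame above
`startThreshold`, tracks the running maximum since the burst opened (the
only online-computable reading of a "local peak"), and closes the burst
at the first frame below 55% of that maximum — that frame is the
exclusive boundary, so the recorded end is the frame before it.
Candidates shorter than 5 frames are detection noise; candidates whose
smoothed values strictly decrease over their first 5 frames (the
smoothing window, configurable) are bursts already decaying when
observation started and are discarded. Surviving intervals are translated
+2 frames (translation, not resizing; clamped at the trace end) to centre
the calls on the underlying events. Missing stretches split a trace into
independently processed segments, so no call ever spans a gap.

The start threshold is a per-experiment constant: the same value must be
used for every condition of a comparison. When not supplied it is derived
from the control condition as 10% of the pooled 99th percentile of the
smoothed traces — tying the gate to the experiment's signal scale while
keeping it far above smoothed noise. Per-burst amplitude is the smoothed
maximum within the called interval; duration is the interval length
(frames, and seconds via the frame interval); total output is the plain
sum of the raw trace over the analysis window (area under the curve at
unit frame spacing). Per-nucleus summaries average over that nucleus's
bursts; a nucleus with no bursts has undefined amplitude and duration
(reported missing), but a well-defined total output and frequency.

# Between-condition statistics

Each burst metric is compared between a condition and the control with a
two-sided Wilcoxon rank-sum test using midranks for ties: exact when the
smaller sample has ≤ 8 observations (the permutation distribution of the
rank sum is computed by dynamic programming over doubled midranks, so
ties are handled exactly), and otherwise a normal approximation with tie
and continuity correction — the two agree to within 0.02 in the
n = 8–12 overlap, which the tests check property-style. Medians are
reported relative to the control. Zero-burst nuclei are included in
total-output and burst-frequency comparisons and excluded from amplitude
and duration, following the definitions of those metrics. P-values are
reported per comparison without correction, mirroring the per-panel
presentation convention of this assay; a Benjamini–Hochberg column is
emitted alongside for transparency. Nuclei are pooled across embryos of a
condition (an embryo identifier can be carried in the summary table for
stratified reanalysis). The report orders trajectory-heatmap rows by
transcription onset — the first frame whose smoothed trace exceeds the
start threshold.

# Pol II ChIP metrics

The pausing index of a gene is the summed per-base coverage in the
promoter-proximal window divided by that of the gene body. Windows are
oriented by strand and half-open in 0-based coordinates: promoter
[TSS−250, TSS+250) (500 bp exactly), body [TSS+500, TES−500); for a
minus-strand gene the TSS sits at the interval's high end and the windows
mirror accordingly. Genes shorter than 1500 bp are removed before any
computation; genes with zero body signal get an undefined index and are
excluded from distributional summaries rather than being assigned
infinity. "Reads in a window" is implemented as summed per-base coverage,
which equals read counts up to a constant factor under uniform read
length — the constant cancels in the ratio. Overlapping genes are scored
independently. Coverage is expected RPM-normalized; `rpmScale()` converts
raw-count tracks.

Per-peak comparison takes the maximum coverage over each peak interval in
control and treatment, removes peaks whose control maximum is below
5 RPM (or whose maximum is zero in either condition), and classifies the
rest by log₂(treatment/control): below −0.1 "diminished", otherwise
"associated" — a partition of the unfiltered peaks.

# Numerical conventions and degenerate inputs

* Tables are TSV (header, UTF-8, `.` decimal, full precision); images are
  16-bit multi-page TIFF, frames-major; configurations are YAML, with
  unknown keys rejected before any computation and the resolved
  configuration written next to the outputs with a version stamp.
* All coordinates in tables are 0-based (row, col); frames are 0-based.
* Blank frames segment to empty label images flagged `degraded`; an empty
  scene yields valid empty tables; an all-identical rank-sum input gives
  p = 1; a dot with no nuclei to attach to is left unassigned with a
  warning.
* Determinism: a master seed fixes simulation, rendering and every
  downstream table; reruns are byte-identical.

# Problem sizes used by the test-suite and acceptance benchmarks

The packaged benchmarks run the demo scene at its native scale
(50 nuclei × 200 frames × 3 z) for segmentation/tracking recovery;
500 Monte-Carlo replicates for fit fidelity at peak SNR 10
($I_0/\sqrt{I_0+\alpha} = 10$); 200 constructed traces for burst
recall/precision; and 100-nuclei condition pairs (180 frames for the
effect benchmark, 120 for each of the 100 type-I replicates) for the
comparison statistics, run at the trace level through the same burst
caller and tests as the imaging path. Unit tests use smaller fixtures of
identical structure. These sizes are the package's chosen study
conditions; the statistical benchmarks (occupancy laws, type-I rates)
are Monte-Carlo quantities and are asserted with sampling-error-aware
bounds, not equalities.

# Known limitations

* Single spot per nucleus: sister-chromatid doublets and multi-allele
  signals are integrated as one dot by the 2-D fit.
* No absolute calibration: intensities stay in arbitrary units; mRNA
  counts per burst are out of scope.
* The burst caller is rule-based by design; hidden-Markov or changepoint
  inference and dwell-kernel deconvolution are deliberate non-goals.
* The threshold scanner and the burst start threshold are data-scale
  heuristics; both are exposed in the configuration and logged, and
  should be fixed once per experiment set.
* Tracking has no division handling, which confines the pipeline to
  interphase windows such as nuclear cycle 14.
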