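---
title: "Methods: from raw capillary traces to residue-level reactivities"
author: "cequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw capillary traces to residue-level reactivities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement and the analysis problem

Chemical probing of RNA (DMS, CMCT, SHAPE acylation) marks structurally
reactive residues with covalent adducts; reverse transcription stops at
each adduct, and capillary electrophoresis (CE) separates the resulting
cDNA fragments by length. Each capillary yields a fluorescence time trace
("electropherogram") in which every residue of the probed sequence appears
as a Gaussian-shaped band. A co-loaded sequencing ladder, fluorescing in a
second spectral channel, runs in the same capillary and serves as a
positional ruler.

Getting from raw multi-channel traces to a residue-by-lane reactivity
matrix requires undoing, in order: instrument offsets (constant and slowly
drifting baselines), run-to-run mobility differences (a global shift and
dilation per capillary plus local, smoothly varying distortions), and the
many-to-one mapping from trace positions to sequence positions (band
annotation). Only then can band areas be quantified. `cequant` implements
this pipeline as composable stages with a checkpointed driver
(`run_pipeline()`), a synthetic-data generator with full ground truth
(`generate_synth()`), and TSV/RDAT exporters.

Deliberately out of scope, and left to downstream analysis: correction for
signal decay along the trace, subtraction of the unmodified-control
background, and final normalization. These steps are performed differently
by different groups and belong after quantification.

# Preprocessing

**Channel selection.** ABIF files carry several spectral channels; which
holds the probing signal and which the ladder depends on dye setup, so
both are configuration (`signal_channel`, `reference_channel`, 1-based).
All `DATA` tags are exposed; the four lowest-numbered tags are the raw
channels on common instruments.

**Trace smoothing.** A short centered moving average (default 5 samples)
is applied to both channels. Fluorescence is sampled much finer than the
band width (sigma of roughly 10 samples at typical spacings), so this
window cuts sample-level detector noise by about sqrt(5) while broadening
a sigma = 10 band by under 1%. The main beneficiaries are the stages that
make *discrete* decisions on the traces — the region-of-interest detector,
the piecewise-alignment dynamic program, and the band-annotation dynamic
program — and the moving-percentile baseline estimator, whose windowed
order statistic is noticeably noisy on raw traces.

**Region of interest (ROI).** The informative sub-range of the run is
found by edge detection on the lane-summed intensity envelope: smooth with
a moving average (default 50 samples), take the first difference, smooth
that as well, and rectify. Smoothing the *signed* difference before taking
the absolute value matters: zero-mean noise cancels, whereas rectifying
first creates a noise pedestal that a relative threshold (default 5% of
the maximum response) can drown in. The first and last window of the edge
response are masked (the filters have no real support there). The ROI is
the smallest range containing all super-threshold samples, padded outward
by one smoothing window. The detector is scale-free; a manual ROI override
is honored verbatim.

**Constant baseline.** Per lane and channel, the 2nd percentile of the
values inside the ROI is subtracted — an order statistic rather than the
minimum, to be robust to single-sample undershoots. Values are not
clipped; small negatives are left for the least-squares stage.

# Alignment

Lanes are aligned on the **reference (ladder) channel** — present in every
capillary and independent of the chemistry — and every fitted transform is
applied to both channels.

**Linear stage.** Each lane is aligned to the first capillary of its
batch, and each later batch's first capillary to the global reference (the
first capillary of the first batch), by exhaustive search over shift
(default -300..300, step 10) and scale (0.95..1.05, step 0.005)
maximizing the Pearson correlation of the warped lane against the
reference over the ROI, followed by one refinement pass at 10x finer
steps. Ties break toward the identity, then the smaller shift, then the
smaller scale, which makes self-alignment return exactly shift 0, scale 1,
score 1. The convention throughout: a transform's warped profile reads
source position `(x - shift) / scale`, i.e. `fit_linear()` returns the
transform you *apply* to the lane to match the reference.

The search is coarse-to-fine in two senses. First, the grid search runs
on *envelope-smoothed* copies of both traces (moving average, default 51
samples, about one band spacing): a sequencing ladder is close to
periodic at the band spacing, so raw-trace correlation has near-tied comb
optima one band apart, and when local distortions additionally decorrelate
the fine structure, a comb-shifted optimum can win outright. Smoothing at
the band-spacing scale suppresses the comb and leaves the band-mass
envelope, which determines the global placement unambiguously. Second,
once the envelope fit has converged, a local refinement (shift within
+-2 samples, scale within +-0.001) re-scores on the *raw* traces, whose
band-scale structure pins shift and scale sharply — the envelope alone is
nearly flat in scale, while the raw comb decorrelates within a fraction
of a band width. The local grid is far narrower than the band spacing, so
the refinement cannot jump the comb.

**Smooth baseline.** After linear alignment, each lane's slowly varying
baseline is estimated by a moving 10th-percentile filter (default window
201 samples) smoothed by a moving average of the same width, and
subtracted. On sparse bands this removes drift and leaves peaks intact; on
dense bands it also removes part of the genuine inter-band signal floor —
a bias the fitting stage compensates for explicitly (below).

**Piecewise-linear refinement.** The ROI is partitioned into windows
(default 100 samples; the last absorbs the remainder); each window may
take an integer offset in [-50, 50]; a window's score is the Pearson
correlation between the offset lane window and the reference window
(zero-variance windows score 0); adjacent windows pay `lambda * |d - d'|`
(default 0.01 per sample). Dynamic programming maximizes total score minus
total penalty; ties break toward the smaller absolute offset, so
self-alignment yields the all-zero path. The optimal path becomes warp
anchors at the window centers, linearly interpolated between, with
identity-slope continuation outside — so warps are strictly monotone and
can never reorder bands. A very large `lambda` provably collapses the path
to the best single global offset.

# Band annotation

Annotation assigns each residue of the probed sequence a trace position,
shared by all aligned lanes (per-lane positions are derived views, not
free parameters). Each lane's modifier contributes a per-residue prior
(`reactivity_mask()`): DMS marks A and C, CMCT marks G and U, SHAPE marks
every residue, a ddXTP ladder marks the template residues complementary to
X (ddTTP at A, ddATP at U, ddCTP at G, ddGTP at C; standard Sanger
pairing, configurable), and unmodified/unknown lanes are uninformative
(0.5 everywhere). Probing lanes keep a 0.1 background weight at unreactive
residues because real traces show residual bands everywhere.

The assignment itself is a dynamic program over candidate positions: the
objective rewards placing residue i where the mask-weighted lane
intensities are high, and penalizes each consecutive spacing `g` by
`mu * ((g - dhat) / dhat)^2` (default `mu` = 1). Candidates are the local
maxima of the summed evidence profile plus a uniform fallback grid (4L
points), so the program never runs out of feasible positions. Lane
intensities are normalized by their global maximum first, which makes the
annotation exactly invariant under rescaling all lanes by a positive
constant.

Two details earn their keep on hard inputs:

* The spacing prior `dhat` is initialized from the median spacing of
  strong peaks of the (lightly smoothed) evidence profile, capped at
  `ROI length / L`, which upper-bounds the true mean spacing. Initializing
  from `ROI length / L` alone mis-registers the program by one band
  whenever the detected ROI is loose.
* The program runs twice: the second pass re-estimates `dhat` as the
  median spacing of the first solution. A truly "running" local median
  inside the DP would make the objective non-separable; the two-pass
  scheme keeps each pass exact for its stated objective.

Manual curation is a first-class operation: `adjust_annotation()` moves a
single residue (strict monotonicity re-validated, neighbors untouched),
and the annotation serializes to an editable TSV that the pipeline driver
picks up when re-run from the annotation stage.

# Peak fitting and quantification

Each aligned lane is modeled as a sum of Gaussians fixed at the annotated
positions. Widths are not fitted: sigma_i is 0.25 times the local median
band spacing (window of 5 spacings), which keeps the per-lane problem a
convex non-negative least squares (NNLS) in the amplitudes — negative
band areas are physically meaningless, and the non-negativity constraint
also stabilizes overlapped fits. Design-matrix columns are truncated at
+-5 sigma (relative column-mass error under 1e-6). The NNLS solve is
`pracma::lsqnonneg()`, a deterministic active-set method.

**Baseline self-consistency.** The smooth-baseline filter of the
alignment stage is defined on the data, so on densely banded lanes the
subtracted baseline contains a signal-dependent component (the smoothed
10th percentile sits on the inter-band troughs, roughly 27% of the local
amplitude level at a 4-sigma spacing). Fitting the filtered trace as if
that floor were instrument background biases all amplitudes downward, and
the bias is not uniform. `fit_peaks()` therefore solves the fixed-point
problem "amplitudes whose model profile, passed through the *same*
filter, reproduces the observed subtraction": iterate a = fit(y +
F(G a)), where F is the filter and G the Gaussian design. The iteration
contracts slowly along smooth amplitude-envelope modes (the filter passes
smooth perturbations almost unchanged, so the data barely constrain
them); 12 iterations are the default, after which the residual bias is
small against the noise floor. Interior iterations use an unconstrained
solve with a single precomputed Cholesky factorization (the design is
shared by all lanes) and a stride-5 evaluation of the percentile filter;
the final amplitudes always come from a full NNLS solve on the
compensated profile.

Band areas are `amplitude * sigma * sqrt(2 * pi)`; the quantification
table has one row per residue and one column per capillary, and both
areas (primary) and raw amplitudes are exported.

# File formats

* **ABIF** (.ab1/.fsa): big-endian binary container; the reader decodes
  all `DATA` tags in tag-number order (right-padding unequal series with
  zeros) and keeps other tags verbatim in metadata; the writer emits a
  minimal valid file (header, directory, one `DATA` tag per channel as
  16-bit integers, `SMPL1` sample name) that the reader inverts exactly.
  Intensities are decoded as signed integers and never rescaled at read
  time.
* **RDAT**: the line-oriented, tab-delimited chemical-mapping exchange
  format (RDAT_VERSION, NAME, SEQUENCE, STRUCTURE, OFFSET, SEQPOS,
  ANNOTATION, ANNOTATION_DATA:n, REACTIVITY:n). Numbers carry 6
  significant digits; output is byte-identical for identical input;
  unknown record types survive a read/write cycle verbatim. The display
  `offset` applies to residue numbering only, never to row indexing.
* Batch layout: one subfolder per sequencer batch (a flat folder is a
  single batch, `batch0`), lanes ordered lexicographically by filename —
  which is what defines "the first capillary of the batch". Zip archives
  are read without the caller extracting them.

# The synthetic-data generator

`generate_synth()` produces experiments with complete ground truth, in
exactly the input layout the pipeline consumes (ABIF files in batch
subfolders). Per lane: planted reactivities `r_i = mask_i * Gamma(1.5, 1)
+ 0.05` (long-tailed, as chemical probing intensities are); band centers
on a monotone quadratic mobility map; the signal channel is the Gaussian
comb of the `r_i`, the reference channel a uniform every-residue ladder;
both are warped by a planted per-lane linear transform plus a smooth
piecewise offset field, then receive a constant baseline, a slow
sinusoidal drift, and i.i.d. Gaussian noise, and are quantized to 16-bit
integers. The ground truth stores the reactivities, the undistorted and
per-lane observed band centers, and the exact *aligning* transform (the
inverse of the planted distortion) per lane.

Defaults are the package's benchmark conditions, chosen once: one batch of
six capillaries (SHAPE, DMS, CMCT, ddTTP, no modification, "other") over
a random 92-nt sequence; 6000 samples per trace; mean band spacing 40
samples with gentle curvature; band sigma 10; intensity scale 1000 counts
per reactivity unit; constant baseline 200, drift amplitude 100; planted
shifts up to +-60 samples, scales within 1 +- 0.01, piecewise offsets up
to +-20 samples; noise sigma 150, which puts the *mean reactive band of a
full-mask lane* (about 1500 counts) at a signal-to-noise ratio of 10.
Signal decay is off by default, mirroring the decision to leave decay
correction downstream.

Two consequences of these conditions are worth stating plainly. First,
bands at a 4-sigma spacing overlap: the profile never returns to zero
between bands, which is what makes the baseline self-consistency loop
necessary. Second, the SNR anchor is per *condition*, not per lane: lanes
whose mask is flat at 0.5 (the unmodified control and "other") have band
peaks around 850 counts and therefore an effective SNR near 5. Their
end-to-end quantification accuracy is correspondingly lower (per-lane
r-squared against planted truth of about 0.985, versus 0.992–0.997 for
the full-mask and ladder lanes). The generator also does not emulate dye
spectral cross-talk, detector saturation, or instrument mobility-file
effects — so passing tests say nothing about those artifacts.

# Numerical choices and degenerate inputs

* Tie-breaks are everywhere toward the identity (alignment) or the
  smaller |offset| (DP), making self-alignment and reruns bit-reproducible;
  the pipeline's TSV/RDAT outputs are byte-identical across runs.
* Zero-variance windows score 0 in the piecewise DP; a zero-variance
  reference or profile is a hard error in the linear fit.
* The constant-baseline order statistic commutes exactly with adding a
  constant; the ROI detector is exactly scale-invariant.
* All-zero profiles fit to all-zero amplitudes without invoking the
  solver; non-finite values in a profile are a hard error.
* The generator refuses configurations whose mobility map is non-monotone
  or whose bands do not fit in the trace.
* Randomness: the generator requires an explicit seed and restores the
  caller's RNG state.

# Problem sizes in the test suite

Unit tests run on compact instances (2–4 lanes, 20–50 residues, traces of
about 2000–4000 samples) built in code at test time. The acceptance suite
runs the full benchmark configuration: the six-condition 92-nt experiment
(552 bands), 20 independent seeds for the planted-warp-recovery and
end-to-end closure properties, 50 random instances for the exhaustive
piecewise-DP oracle, and byte-level determinism checks on complete
pipeline runs.

# Known limitations

* Widths are tied to band spacing; if true band width does not scale with
  spacing (e.g. strong mobility curvature at constant diffusion width),
  the width model is mildly misspecified, which couples with band overlap
  into percent-level area errors.
* The baseline self-consistency iteration corrects the dominant
  floor-subtraction bias but converges slowly along smooth amplitude
  modes; a few counts of structured bias remain at the default iteration
  count.
* Flat-mask (control) lanes at the default noise level sit below the
  SNR-10 regime and quantify at r-squared about 0.985 against planted
  truth, not 0.99.
* Signal decay, background subtraction, and normalization are explicitly
  not performed.
* Annotation assumes at least moderately regular band spacing; it has no
  model for missing bands (deletions) or compressions beyond what the
  spacing penalty absorbs.
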