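---
title: "Quantifying the axonal membrane periodic skeleton from STED images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the axonal membrane periodic skeleton from STED images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmps)
```

## The measurement problem

Mature axons carry a sub-membranous lattice of short actin rings connected
by spectrin tetramers — the membrane-associated periodic skeleton (MPS) —
with a longitudinal spacing of about 190 nm. The lattice is below the
diffraction limit and only becomes visible with super-resolution
microscopy such as STED (~50–60 nm lateral resolution), where
phalloidin- or βII-spectrin-stained axons show regular transverse stripes.
Judging "how much" of an axon carries a visible lattice, and how well
organized that lattice is, by eye is slow and subjective. `axonmps`
automates the measurement:

1. **Axon detection.** Foreground pixels are those above
   `median + k · MAD` of the lightly smoothed image (k = 3 by default),
   after removing 8-connected objects smaller than 0.5 µm². Robust
   background statistics are used deliberately: STED fields are mostly
   empty, and histogram-split thresholds (Otsu) place the cut inside the
   background mode when the foreground is sparse.
2. **Local orientation.** The axis of each axon is estimated from the
   structure tensor (Gaussian-smoothed gradient outer products, scale
   200 nm). The image is first smoothed with σ ≈ 95 nm — half the lattice
   period — before taking gradients. This step matters: on lattice-bearing
   axons the 190 nm stripes dominate the raw gradients and the tensor
   would report the stripe normal, i.e. an axis rotated 90° from the
   axon. Averaging over half a period removes the stripes while the axon
   backbone remains a smooth ridge. Coherence (the normalized eigenvalue
   contrast) is computed from the unsmoothed-gradient tensor, where
   isotropic noise is not pre-correlated by the smoothing; it is reported
   for inspection but low-coherence segments are still scored — the
   orientation search below absorbs moderate angular error.
3. **Tiling.** A non-overlapping grid of 1 µm × 1 µm squares anchored at
   the image origin; squares whose axon-mask fill fraction reaches
   `min_fill` are scored, each carrying the circular median of the
   orientation angles over its masked pixels.
4. **Lattice correlation.** The model is a one-dimensional comb of
   Gaussian peaks (σ = 25 nm) spaced 190 nm apart along the axon axis and
   constant across it, standardized to zero mean and unit variance. A
   segment's score is the maximal Pearson correlation between its raw
   pixels and the model over a grid of lattice phases (step = ¼ pixel)
   and orientation offsets (±15° in 1.5° steps) around the segment
   orientation. Constant segments score 0 and are flagged degenerate;
   they stay in the abundance denominator.
5. **Summary.** A segment is *MPS-positive* when its correlation is
   strictly above the threshold (0.17 by default — the shipped value
   corresponding to visually discernible periodicity). *MPS abundance* is
   the fraction of scored segments that are positive; *MPS correlation*
   is the mean correlation of the positive segments and reflects how well
   organized the lattice is where it is present.

Correlation is computed over **all** pixels of the square, not only
masked ones. The model's flat inter-peak baseline then penalizes
non-periodic structure, and the score does not inherit artefacts of the
detection mask. The price of this choice is dilution: a square whose axon
clips only a corner cannot reach the threshold even when its lattice is
perfect. We measured this on synthetic ground truth — segments with fill
fraction between 0.1 and 0.2 were positive in under 3 % of cases on
noise-free, fully periodic axons — and therefore require
`min_fill = 0.25` by default: a segment must contain appreciable axonal
material to enter the abundance denominator at all. The parameter is
exposed for users who prefer a more inclusive (and systematically lower)
abundance.

### Search grid and numerical choices

* Phase step defaults to ¼ pixel and the orientation step to 1.5°. At
  full-pixel phase steps a worst-case half-step miss already costs a few
  percent of correlation (the comb autocorrelation at a 10 nm lag is
  ≈ 0.96), which is more than the agreement we demand between the grid
  search and an exhaustive 1 nm / 1° search (0.02). Both steps are
  configurable through `pattern_config()`.
* The comb is evaluated through a 0.25 nm periodic lookup table; the comb
  slope bounds the induced error at ~3·10⁻³ of the peak amplitude, far
  below the correlation tolerances above. For one orientation, all phases
  are scored at once as a circular cross-correlation between the table
  and 1D histograms of the patch binned by its along-axis coordinate,
  which is what makes the fine search grid affordable.
* Ties in the search are broken toward the smallest phase, then the
  smallest absolute orientation offset.
* Thresholding is strict (`correlation > threshold`); a score exactly at
  the threshold is negative.

## Period estimation

Line profiles are sampled by bilinear interpolation at pixel-size steps,
averaging three parallel lines one pixel apart (the common practice when
tracing rings by hand). Peaks are local maxima — a plateau of equal
values counts once, at its centre, which matters because a peak lying
exactly halfway between two samples produces a two-sample plateau — with
prominence at least 10 % of the profile's dynamic range and mutual
separation of at least 100 nm (below the 190 nm target, above the scale
of noise bumps). Each peak is refined by a least-squares quadratic fit
over ±2 samples, capped at ±50 nm (≈ 2σ of a ring): at coarse sampling a
wider window reaches into the Gaussian tails, where a parabola is a poor
model and biases the vertex by more than a nanometre. A refined vertex
falling more than one pixel from its integer maximum is rejected as a fit
failure. The mean consecutive peak distance is the segment's period; an
estimate is `valid` when it rests on 4–7 peaks (a line crossing about 4–5
consecutive rings), and `condition_period()` pools at least 15 valid
segment periods into a condition-level mean ± SD.

The complementary manual criterion is also implemented:
`count_periods()` calls a profile positive when it holds a run of at
least 4 consecutive inter-peak gaps within 190 ± 40 nm.

## Fragmentation quantification

Degenerating axons break into fragments and bead-like debris. From a
binarized image (Otsu on 256 histogram bins, or a fixed cutoff; a
constant image yields an empty mask with a warning), total axonal area is
the foreground pixel count, and components smaller than
`min_particle_area_um2` (default 20 µm²; the appropriate value depends on
magnification and axon calibre, and the cutoff used is recorded in the
report) are counted as excluded particles. The report keeps the raw
per-image numerator and denominator; normalizing "percent unfragmented"
across conditions requires paired control images and is left to the
caller.

## The synthetic-image simulator

All quantitative validation runs against `make_axon_layout()` /
`render_sted_image()`, which emulate the imaging substrate with known
ground truth:

* **Geometry.** Smooth random polylines (heading change sd 2.5° per
  250 nm step) confined to the field, with transverse Gaussian width
  σ = 150 nm. Every full 1 µm stretch of centre line is independently
  labelled MPS-positive with the requested occupancy.
* **Lattice.** In positive stretches, rings are Gaussian ridges
  perpendicular to the local axis (longitudinal σ 25 nm, transverse
  extent = the axon width), spaced 190 nm with optional gap-wise jitter.
  The phase is drawn once per run of consecutive positive stretches and
  the train continues across their boundaries — a physical lattice does
  not reset every micron, and with zero jitter consecutive rings are
  spaced exactly 190 nm apart.
* **Optics and noise.** The structural image is convolved with a Gaussian
  PSF (σ = 25 nm ≈ 60 nm FWHM), then Poisson shot noise on scaled
  intensities and additive Gaussian read noise are applied. Defaults for
  the validation conditions are ring amplitude 100, backbone 30, Poisson
  scale 1 and read noise sd 10 — peak signal-to-noise around 7, a
  moderately noisy STED acquisition. Longitudinal "actin trail" fibres
  (bright intra-axonal F-actin bundles a few µm long) can be added; they
  are deliberately non-periodic confounders.
* **Study geometry.** Validation fields carry ~0.25 µm of axon per µm²
  (e.g. 100 µm of axon in a 20 µm field), sparse enough that axon
  crossings are rare — matching how such images are acquired in practice,
  where analysts favour regions with non-bundled, non-superimposed axons.

What the simulator does *not* model: labelling stochasticity and
photobleaching, realistic (non-Gaussian) STED PSF shapes including the
depletion doughnut's side lobes, sample drift, and biological
heterogeneity of ring spacing along one axon beyond i.i.d. gap jitter.
Passing the synthetic recovery suites therefore demonstrates that the
*algorithm* measures what it claims on images whose structure is known;
it does not certify performance on any particular microscope's data,
where threshold and peak-width settings may need recalibration — which is
what `calibrate_threshold()` is for, reconstructing a threshold from
labelled example segments by maximizing balanced accuracy over candidate
midpoints between adjacent scores.

## Validation summary (computed by the test suite)

* A noise-free 6-peak comb at 190 nm spacing, 20 nm/px, is recovered
  within 1 nm; across spacings 150–250 nm and pixel sizes 10–30 nm the
  estimator stays within 1 nm of truth, and with 10 % Gaussian noise the
  mean absolute error over 60 profiles stays below 5 nm.
* Segment scores match an exhaustive 1 nm / 1° brute-force search within
  0.02 on random noisy lattice patches.
* Measured abundance recovers ground-truth occupancy 0/0.25/0.5/0.75/1
  within ±0.10 (five seeds per level, ≥ 200 µm of axon per seed, noise as
  above), and the mean correlation of truly periodic segments decreases
  monotonically with ring-spacing jitter over 0–40 nm.
* Fragment-field areas are reproduced exactly and area is conserved by
  the particle-exclusion arithmetic.

Problem sizes in the test suite (field sizes, seed counts, axon lengths)
are the package's chosen validation conditions; they keep a full run in
the tens of minutes on a single core.

## Known limitations

* Orientation is undefined near axon terminations (a tip looks like a
  blob at the tensor scale); affected segments rely on the ±15° search
  range.
* Crossing or bundled axons inside one square lower its correlation; the
  method reads them as disorganization, as would an observer applying
  the periodicity criterion to the mixed pattern.
* Abundance is a per-segment proportion: it is only comparable across
  images analysed with the same `segment_um`, `min_fill` and threshold.
* The 0.17 default threshold is an empirical constant for
  βII-spectrin-type STED data; other stains, resolutions or pixel sizes
  warrant recalibration.
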