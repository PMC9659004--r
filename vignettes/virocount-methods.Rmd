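---
title: "Methods: motor counting and motility quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motor counting and motility quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virocount)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter, what the synthetic generators do
and do not emulate, and the numerical and design choices that were
genuinely open.

## 1. Fluorescence molecule counting

### Concentric-ROI intensity measurement

`measure_corrected_intensity()` integrates raw counts over an inner disc of
8 px diameter centred on a spot and estimates the local background from the
surrounding annulus out to a 10 px outer disc:

$$ I = I_\mathrm{in} - (I_\mathrm{out} - I_\mathrm{in})
       \frac{A_\mathrm{in}}{A_\mathrm{out} - A_\mathrm{in}} $$

where the $A$ are pixel counts of the actual disc masks. A pixel belongs to
a disc when its centre lies within the disc radius of the (sub-pixel)
centroid — a deliberately simple membership rule that makes the measurement
brute-force checkable (the test suite reproduces it by per-pixel background
subtraction). On a flat background the correction is exact; a locally
linear ramp cancels to first order because the annulus mean equals the ramp
value at the centroid. Two consequences worth knowing:

* Corrected intensities are unbiased but can be negative on pure noise.
  They are retained (clipping would bias cohort means upward) and flagged.
* A small fraction of spot flux falls in the annulus and is subtracted as
  "background". For a Gaussian PSF with $\sigma = 1$ px the net loss is
  about 0.1%; at $\sigma = 1.3$ px it grows to ~2.5%. The 8/10 px
  diameters are taken at face value in pixels regardless of pixel size (the
  ROI diameters are arguments everywhere, so users can match their optics).
  Because the same loss applies to standards and unknowns, molecule counts
  are insensitive to it — only absolute photon bookkeeping is affected.

Spots whose outer disc overlaps another detection's inner disc are flagged
`crowded` and excluded from calibration summaries, since their annulus is
contaminated by the neighbour's flux.

### Detection

`detect_spots()` is a scale-normalised Laplacian-of-Gaussian blob detector
at $\sigma = d/(2\sqrt2)$ for an expected diameter $d$, with strict
8-neighbour maxima, an optional 3×3 median prefilter, and sub-pixel
refinement by 1-D quadratic interpolation of the response. Quality is the
response magnitude, so raising the threshold can only remove detections
(monotonicity is tested).

### Calibration and motor arithmetic

`fit_calibration()` fits a through-origin least-squares line to corrected
intensity versus fluorophore copy number of nanocage standards
(24/60/120/180 copies). The fit uses per-species mean intensities, as such
standard curves are conventionally plotted; a `per_spot` flag pools
individual spots instead. The slope is $s = \sum_N N\,\bar I_N / \sum_N
N^2$ and $r^2$ is the uncentred coefficient appropriate for a no-intercept
model. Molecule counts are $I/s$; kinesin-1 complexes are molecules/2 (two
tagged heavy chains per heterotetramer); expression correction multiplies
the cohort mean by the parental/knock-in antibody intensity ratio (a ratio
of cohort means — the simplest estimator consistent with a reported
"x-fold higher" difference) and rounds to the nearest integer. The
published corrected counts are reproduced from the published rounded cohort
means (65 and 115 complexes); an unrounded path is available by passing the
unrounded mean.

### Surface areas and densities

`ellipsoid_surface_area()` uses the Thomsen approximation with $p =
1.6075$, exact in the sphere limit and within ~1.1% of the true area for
moderate axis ratios; a dense-trapezoid quadrature of the parametrised
surface element is provided as a verification mode and agrees with the
Thomsen value to well under 1.2% over the tested shapes. For the virion
dimensions used here the approximation is ~0.03% above the exact area.
Note that the published area values are slightly (0.01–0.09%) above what
either formula yields from the published *rounded* axis lengths; they were
evidently computed from unrounded measurements, so agreement at the
nearest-integer level from rounded inputs is not attainable. Motor density
uses `floor(area / n_complexes)` — the floor, not rounding, matches the
published density figures when computed from the published areas.

## 2. Trajectory analysis in cells

### Linking

`link_spots()` follows the two-pass "simple LAP" structure: optimal
frame-to-frame assignment (an in-package O(n³) Hungarian solver, validated
against brute-force permutation search) minimising summed squared
displacement among candidate pairs within 0.8 µm, with `max_link²` as the
alternative no-link cost; then a gap-closing pass joining track ends to
later track starts across ≤ 5 missing frames within `max_link·√(gap+1)` —
a diffusive scaling of the search radius, chosen because a particle
invisible for g frames has had g+1 frames of motion. Gap-closed frames get
linearly interpolated positions and are marked so MSD fits can skip them.
This is per-frame-pair optimal, not a global spatiotemporal optimum — the
same trade-off the widely used trackers make.

### Motion-state segmentation

`classify_segments()` works at two scales, which is the central design
choice of this module:

* **Active transport is a local property.** Each point gets a windowed MSD
  log-log slope $\alpha$ (window 15 frames = 1.5 s at 10 Hz, lags 1–5) and
  a windowed straightness (net/path displacement). A point is active when
  $\alpha \ge 1.3$ and straightness ≥ 0.6. At 0.6 µm/s with 30 nm
  localization noise these windowed features are noisy; the thresholds were
  set from measured feature distributions on simulated regimes to hold the
  false-positive rate on diffusive motion near 0.2% while keeping ≥95% of
  genuine active points (an $\alpha$ cut at 1.5, for comparison, loses
  ~20% of active points at this SNR).
* **Confinement and anomalous diffusion are segment properties.** A 1.5 s
  window cannot tell a confined walk from free diffusion when the
  confinement radius is comparable to the diffusion length per window, and
  single-window MSD exponents have very heavy tails. Each maximal
  non-active stretch is therefore labelled as a whole: the MSD over lags
  1..min(n/5, 40) is corrected for the localization-noise floor (intercept
  of a short-lag linear fit, clamped to [0, MSD(1)]), and two features
  decide the label. A scale-free *escape ratio* — squared extent of the
  point cloud over n·MSD(1) — is ≤ 1 when the walk could not leave a
  confinement zone and > 1 for free diffusion (measured distributions:
  confined 5th–95th percentile 0.34–0.60 vs diffusive 1.46–4.5 on 20 s
  stretches); below `esc_confined = 1` the stretch is confined. Otherwise
  the full-lag slope $\alpha$ calls subdiffusion below 0.8 and normal
  diffusion above.

Active/passive stretches shorter than 5 frames are absorbed into their
longer neighbour, so segments tile the track exactly. Active velocity is
net displacement over duration — robust to localization noise, which
inflates path length but not net displacement; on noise-free ballistic
tracks the estimator is exactly unbiased.

Known limitation: below ~10 s of passive data the localization-noise floor
and genuine subdiffusive curvature of the MSD are statistically
confounded, so short subdiffusive stretches tend to be labelled normal
diffusion. The 0.8 boundary deliberately favours normal diffusion at short
segment scale; at whole-track scale (≥ 20 s) fractional Brownian motion
with H = 0.3 is recognised ~85–90% of the time. All five thresholds and the
window are exposed (`classify_thresholds`).

### Motile counts

`count_motile()` applies the standard dispersion readout: a track is motile
when its net displacement within a 60 s window exceeds 3 µm. A
displacement filter (`filter_by_displacement()`, > 1 µm) removes
stationary particles before state analysis; a non-positive threshold
disables it.

## 3. In vitro motility

`build_kymograph()` resamples a polyline path at one column per pixel of
arclength and averages `line_width_px` bilinear samples perpendicular to
the path, giving the familiar position–time image. Run extraction,
however, operates on along-path position traces (detections projected onto
their microtubule) rather than on image-space line tracing:
`extract_runs()` finds maximal stretches where the 3-frame-smoothed speed
exceeds 0.1 µm/s for ≥ 3 s, trims boundary frames whose raw speed does not
clear the threshold (smoothing otherwise leaks stationary frames into the
segment and biases the fitted slope low by ~3%), and reports the
least-squares slope of position versus time. This operationalises the
manual "constant-velocity segment" measurement deterministically and
oracle-checkably, while the kymograph image remains available for
visual inspection. A virion that stalls at the microtubule tip ends its
run at arrival (the stationary tail is not part of the run length) and is
scored `reached_end` when the final position is within `end_tolerance`
(0.5 µm) of a tip. Motility rates are counts per imaging minute per
millimetre of microtubule; directionality is the sign of the fitted slope
against the microtubule's polarity annotation.

## 4. The synthetic generators

All four generators emit complete ground truth (`SceneTruth`-style tables)
and are bit-reproducible under a fixed seed (one `set.seed()` per scene;
objects are generated in a fixed order, so per-object sub-streams would add
nothing).

* **Spot scenes** render integrated 2-D Gaussian PSFs (difference of
  normal CDFs at pixel edges — flux on the grid is exact, unlike point
  sampling), over a flat or linearly ramped background, with Poisson shot
  noise on photons followed by Gaussian read noise and a constant camera
  offset at unit gain. Defaults — 0.1 µm pixels, σ = 1 px, 100
  photons/fluorophore, 50 photons/px background, offset 100, read noise
  2 counts — represent a high-NA spinning-disc system imaging bright
  fluorescent-protein assemblies; actual instrument gains/offsets are not
  published for this assay class, so the defaults are recorded in every
  scene's optics metadata. `shot_noise = FALSE` gives the exact expected
  image for flux-conservation tests.
* **In vitro movies** translate spots at constant speed along straight
  microtubule segments at 1 frame/s, with optional per-frame localization
  jitter, stalling at the tip or detaching per the planned end behaviour.
* **Trajectories** realise the four motion states at 10 Hz: straight-line
  active motion; Gaussian random walks with per-axis step variance 2·D·dt;
  subdiffusion as fractional Brownian motion (H < 0.5, fGn by Cholesky
  factorisation of the exact increment covariance); confinement as a
  random walk radially reflected in a disc. The generative models for the
  latter two are the simulator's own choice (the qualitative state
  taxonomy does not prescribe them) and are recorded in the truth labels.
* **Cell scenes** rasterise a simple polygon at the pixel grid and place
  spots uniformly or with prescribed interior/peripheral counts, with
  truth labels from exact point-to-polygon distances.

What the generators deliberately do **not** emulate: 3-D PSFs, spectral
bleed-through, photobleaching, motor stochasticity (planted runs have
constant speed), microtubule curvature, and cell-shape complexity beyond
polygons. Passing the recovery suites therefore demonstrates that the
estimators are correct and unbiased *under the stated models*, not that
they are robust to every pathology of real data.

## 5. Problem sizes, tolerances and degenerate inputs

Recovery suites use sizes chosen to make Monte-Carlo tolerances
meaningful: 50 spots per nanocage species for 2% slope recovery; 200
planted runs for 5% in vitro velocity recovery; 100 tracks × 15 s at 10 Hz
for 8% in-cell velocity recovery; 20 seeds × 3 tracks per regime for the
90% state-accuracy property; 1000 pure-noise measurements for the
zero-bias bound (3 standard errors). Mask erosion uses the exact Euclidean
distance transform (image borders count as background); spots exactly on
the interior boundary count as interior (strict inequality on distance).
Empty spot tables, zero-speed plans, bands wider than the cell inradius,
and polarity-free run summaries are all defined outcomes rather than
errors, and are covered by tests.
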