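---
title: "pHLIM methods: phasor FLIM, calibration, and per-vesicle pH quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pHLIM methods: phasor FLIM, calibration, and per-vesicle pH quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phlimr)
```

## The measurement problem

Sub-cellular pH — cytosol near 7.4, lysosomes below 5 — is usually read out
from pH-sensitive fluorophores by their emission *intensity*. Intensity-based
readouts have two structural problems: the signal confounds sensor
concentration with pH (forcing a second reference fluorophore), and the
absolute measurement error stays roughly constant while the signal collapses
at acidic pH, so the relative error — and the pH uncertainty after inverting
a sigmoidal calibration — explodes exactly where lysosomal biology happens.

pHLIM sidesteps both problems by reading out the *fluorescence lifetime* of
the red fluorescent protein mApple, which falls approximately linearly from
2.2 ns at pH 7.4 to 1.3 ns at pH 4.6 (~0.32 ns per pH unit). Lifetime is
concentration-independent, needs no reference channel, and a linear
calibration keeps the inverse-prediction uncertainty flat across the
physiological range. `phlimr` implements the full analysis chain for such
data, plus a synthetic generator so every stage is testable without a
microscope.

## Phasor analysis

Raw fast-FLIM data are per-pixel photon-arrival histograms (TCSPC cubes).
Rather than fitting multi-exponential decay models pixel-by-pixel, each
pixel is mapped to its first-harmonic Fourier coordinates — the *phasor* —

$$G = \frac{\sum_t c_t\cos(\omega t)}{\sum_t c_t},\qquad
  S = \frac{\sum_t c_t\sin(\omega t)}{\sum_t c_t},$$

with $\omega = 2\pi f_\mathrm{rep}$ (0.50265 rad/ns at 80 MHz) and $t$ the
bin-centre time. The transform is fit-free and exactly invariant to photon
count scaling. Single-exponential decays fall on the universal semicircle
$(G-\tfrac12)^2 + S^2 = \tfrac14$; mixtures fall inside it. For mApple, G
rises linearly as pH falls, which is the whole basis of the method.

Numerical choices:

* **Bin-centre convention** for the Fourier sums minimises discretisation
  bias (relative error $\sim(\omega\Delta)^2/24$, about $4\times10^{-4}$ at
  64 bins over a 12.5 ns period — far below the calibration tolerances).
* **Zero-photon pixels are masked, never NaN-filled**, so photon-weighted
  denominators stay defined.
* The instrument response is treated as an ideal pulse at $t=0$; a constant
  time offset argument is available, and in practice the empirical
  calibration absorbs any fixed instrument phase.

The **fast lifetime** reported per pixel is the phase lifetime
$\tau_\varphi = S/(\omega G)$. This convention was chosen deliberately: the
published anchor pair (image-mean $\tau$ = 2.2 ns *and* G = 0.39 at pH 7.4,
80 MHz) is inconsistent with an arrival-time-mean estimator for any
non-negative exponential mixture, but is exactly realisable under the
phase-lifetime convention. It is also what fit-free phasor practice reports.

Image-level summaries are photon-weighted means over valid pixels
(`image_weighted_G()`, `image_weighted_lifetime()`), and `modal_G()` reports
the centre of the heaviest photon-weighted histogram bin, ties broken toward
lower G (higher pH). Calibration wells are spatially binned 8×8
(`spatial_bin()`, non-overlapping block summation, photon-conserving) before
these summaries; besides matching standard practice for uniform wells, the
binning suppresses the small positive ratio bias of per-pixel
$S/(\omega G)$ at low counts.

## Calibration

**G → pH.** `fit_g_calibration()` regresses pH on G by ordinary least
squares — orientation chosen so conversion is direct evaluation — and
stores the band state $(n, \bar g, S_{gg}, s)$ so `g_to_ph()` can report
the 95% prediction half-width

$$\mathrm{hw}(g) = t_{0.975,\,n-2}\, s\sqrt{1 + 1/n + (g-\bar g)^2/S_{gg}}.$$

The package's reference line, `default_g_calibration()`, passes through the
five image-level anchor pairs (0.39, 7.4) … (0.62, 5.1), which are exactly
collinear: pH = 11.3 − 10 G. Conversions outside the calibrated G range are
refused by default (`allow_extrapolation` overrides); the per-vesicle table
allows extrapolation but flags affected rows, because shot noise
legitimately pushes individual vesicle G values slightly past the anchors.

**Intensity → pH.** For the uncertainty comparison, normalised emission
intensities are fitted with a base-10 four-parameter logistic in pH
(the standard dose–response convention for a log-scale variable):
$I(\mathrm{pH}) = b + (t-b)/(1+10^{(m-\mathrm{pH})h})$. The defaults of the
simulator's model (bottom 0.07, top 1.0, midpoint 6.0, hill 1.0) were set
once to satisfy the sensor's published ~90% intensity drop between pH 7.4
and 4.6 (the exact model value is 89.0%) and are overridable.

**Inverse-prediction uncertainty.** `interpolated_ph_uncertainty()` returns
the half-widths of the pH interval whose predicted measurement band contains
the observed value. For the linear G calibration this is the prediction band
itself — flat in pH up to band curvature. For the 4PL it is asymmetric and
found by root search; where the band fails to exclude an asymptote the
half-width is reported as `Inf`, which is the honest statement: at the
acidic plateau an intensity measurement carries *no* lower bound on pH. The
two half-widths are summarised by their mean, and both are returned.

## Vesicle detection and post-filtering

Vesicles are detected in the photon-count image. The classical backend:

1. percentile normalisation (low 25, high 99.8, clipped to [0, 1]);
2. scale-normalised multi-scale Laplacian-of-Gaussian blob enhancement over
   radii 2–8 px (0.27–1.1 µm at 133 nm pixels);
3. watershed partition of the above-noise response into candidate basins —
   touching blobs split along the response valley, so candidates never share
   pixels (the `overlap_threshold = 0` semantics);
4. per-basin probability proxy $1 - e^{-\ln 2\,\cdot\, \mathrm{peak}/(5\sigma_{bg})}$
   (a peak 5 noise SDs above the floor scores 0.5), thresholded at 0.5.

The noise floor $\sigma_{bg}$ is estimated from the *negative* side of the
LoG response only: blob responses are strictly positive, so the negative
tail is uncontaminated background noise. Estimating it from the full map
inflates the floor in vesicle-dense fields and costs dim detections.

A trained star-convex deep detector can substitute for the classical backend
through `backend = "external-model"`, which adopts any externally produced
label image; every downstream quantity depends only on the label mask.

Post-filters mirror the published analysis settings: pixels under 15
photons are removed from regions, then regions larger than 2 µm²
(≈113 px at 133 nm pixels) are discarded (`filter_labels()`);
`erode_labels()` performs label-wise 3×3 binary erosion (a pixel survives
only if its full neighbourhood carries the same label, so labels can never
merge); `double_positive_mask()` classifies A-channel vesicles by ≥1 pixel
of overlap of their *original* extents with the *eroded* partner mask — the
erosion demands genuine coincidence rather than adjacency. Regions are
4-connected; boundary-touching vesicles are retained; coordinates are
0-based (row, col).

## Per-vesicle quantification

For each vesicle the photon-weighted mean G

$$\bar G_k = \frac{\sum_{xy\in k} P_{xy} G_{xy}}{\sum_{xy\in k} P_{xy}}$$

is converted to pH through the calibration; the intra-vesicle SD of
per-pixel pH (same calibration, no re-thresholding inside regions) reports
heterogeneity within the compartment. Image summaries use the *unweighted*
mean over vesicles (each vesicle is one observation, matching the dotted
mean lines of per-vesicle histograms; a photon-weighted variant sits behind
a flag), the modal pH (0.1-unit bins, ties toward lower pH), and the
"majority interval" — the 0.125/0.875 quantiles with the
linear-interpolation convention. Treatment arms are compared per timepoint
with the classic equal-variance two-sample t-test on replicate means, and
cargo–pH association is reported as both Pearson's r and Spearman's ρ
(the field does not standardise on one).

## The synthetic generator

`photophysics_model()` encodes the sensor: linear phase lifetime
(2.2 → 1.3 ns across pH 7.4 → 4.6), linear G (= (11.3 − pH)/10), and 4PL
relative intensity. A decay realising a given pH is constructed by the
**chord decomposition** (`decompose_biexponential()`): fixing a short
component at 0.5 ns, the chord from its semicircle point through the target
(G, S) meets the circle again at the long component, and the interior
division ratio gives the intensity fraction — by phasor linearity the
photon-weighted mixture lands exactly on the target, and both the G and
$\tau_\varphi$ anchors are honoured simultaneously. The true mApple decay is
unknown beyond its anchors; the bi-exponential is a stand-in constrained to
reproduce them. Photon arrival times are drawn from the mixture *wrapped
into one laser period* — at 80 MHz with τ ≈ 2 ns, photons from earlier
pulses fold into the window and the wrap correction is material to G.

Scenes render vesicles as Gaussian-profile discs (profile σ = r/2, truth
disc of radius r, uniform radii 2.5–5 px — the 0.7–1.3 µm diameter scale of
late endosomes/lysosomes) over a dim cytosolic background (1 photon/px at
pH 7.4), with Poisson pixel counts and per-photon arrival sampling. The
photon budget of a vesicle is scaled by the model's relative intensity at
its pH, so acidic vesicles are dimmer, as for the real sensor. An optional
cargo channel renders coincident intensity discs with a configurable
pH-coupling coefficient (default 0 — the null scenario).

**Photon budget default.** The weighted-G estimator's per-vesicle precision
is shot-noise limited: $\mathrm{SE(pH)} = |\mathrm{slope}|\sqrt{\mathrm{var}(\cos\omega t)/N}
\approx 10\sqrt{0.44/N}$ near pH 7.4 (var ≈ 0.24 at pH 4.6). The default
nominal budget of 3×10⁴ photons per vesicle (a few hundred photons at the
brightest pixels, the regime high-flux fast-FLIM acquisition with line
accumulation operates in) leaves ≈3×10³ photons in the dimmest pH 4.6
vesicles and a predicted per-vesicle SE of 0.04–0.08 pH across the range.
Per-vesicle pH heterogeneity in time courses defaults to SD 0.15, the scale
of vesicle-to-vesicle spread within one compartment class.

What the generator does *not* emulate: optical PSF blur, detector
afterpulsing, pile-up, dark counts, 3-D geometry, cell-to-cell expression
variability, and motion. Passing tests therefore demonstrate correctness of
the *analysis* under the stated photophysics and Poisson statistics, not
robustness to every property of real microscopy data.

## Problem sizes and determinism

The shipped tests and the acceptance script use 100×100-pixel uniform wells
(~5×10⁶ photons), 256×256 scenes of 100 vesicles, 128×128 time-course
scenes of 40 vesicles with 3 replicates per arm, and ~900 pooled vesicles
for the cargo null — sizes chosen so each statistical assertion has clear
margin over its tolerance while a full run stays interactive. Every
generator is a pure function of (spec, model, seed); per-timepoint seeds
are derived from the scene seed so time courses are reproducible while
timepoints stay independent.

A note on null-hypothesis checks: with four timepoints tested at α = 0.05,
a correctly calibrated null yields at least one rejection in ~19% of runs.
The null assertions therefore bound the *rejection rate* (at most one of
four timepoints, and ~nominal rates across repeated seeds) rather than
demanding zero rejections — a zero-rejection requirement would fail a
perfectly correct implementation one run in five.

## Known limitations

* The phase-lifetime convention is a documented design choice; instruments
  using a different fast-lifetime estimator will agree on G (and hence pH)
  but not necessarily on reported ns values.
* The classical detector is tuned for diffraction-scale puncta on dim
  backgrounds; densely packed or strongly textured cells are better served
  by a trained external model via the adapter.
* Calibration extrapolation is refused rather than propagated, except in
  the flagged per-vesicle path.
* Decay cubes are stored as uint16 TIFF pages (counts above 65535/pixel/bin
  are rejected); phasor pages use rescaled 32-bit storage, lossless to
  ~1e-9.

## A minimal worked run

```{r example, eval = FALSE}
model <- photophysics_model()
scene <- simulate_cell_scene(scene_spec(n_vesicles = 100, seed = 1), model)
res <- analyze_scene(scene)
res$summary
plot_ph_histogram(res$vesicles)
```
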