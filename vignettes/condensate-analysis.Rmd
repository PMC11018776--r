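---
title: "Condensate versus aggregate: models and methods in condensr"
author: "condensr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensate versus aggregate: models and methods in condensr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`condensr` quantifies whether a fluorescent focus in a rod-shaped bacterium
behaves like a phase-separated condensate (reversible, with a coexisting
dilute phase and molecular exchange) or an insoluble aggregate. This
vignette is the package's account of the underlying models: what each
statistic assumes, which knobs matter, what the synthetic-data generator
does and does not emulate, and where we made judgement calls.

## The camera model

Every simulated image passes through an explicit EMCCD forward model
(`CameraModel`):

1. expected photons per pixel → photoelectrons by Poisson sampling
   (quantum efficiency folded into the photon budget);
2. multiplication by the realized EM gain, `nominalEmGain × emGainFactor`;
3. division by the conversion gain `g` (electrons per intensity count);
4. addition of a bias offset and Gaussian read noise.

Defaults are a bias of 100 counts, read noise 2 counts, `g = 1.40`
e⁻/count, EM-gain factor 0.15, and a pixel size of 0.066 µm (so three
pixels span 198 nm). EM excess (multiplicative) noise is deliberately not
modelled: the calibration estimators target first and second moments at the
scales where shot noise dominates, and the added realism would buy nothing
for the round-trip tests while coupling them to one more nuisance
parameter. The same reasoning excludes pixel-response nonuniformity: the
calibration procedure (frame-pair differencing) is designed to cancel it,
and the generator documents rather than hides that the cancellation is
exact here.

With this model, `variance(counts) = mean(counts − bias)/g` for flat
fields, so the conversion-gain fit (`fitConversionGain`) regresses mean on
variance and reports the slope; read-noise variance is additive and lands
in the intercept. The orientation of that regression is the one the
simulator validates: with the other orientation, recovery fails for any
`g ≠ 1`, which is exactly what the unit tests would catch. The EM-gain fit
(`fitEmGainFactor`) is forced through the origin because a single
proportionality factor, not an affine law, is the quantity of interest;
nominal gains outside 5–600 are excluded because linearity is only assumed
on that range.

## Rendering cells and foci

Cells are spherocylinders (cylinder with hemispherical caps) rasterized on
the pixel grid; the label mask equals the rendered footprint exactly, which
stands in for a trained segmenter (`segmentFallback` provides an
Otsu-based demo segmenter, but simulated masks are ground truth). Total
cell signal is `copy_number × photonsPerMolecule` — photon conservation is
exact with noise off, and division splits copy numbers exactly, which is
what makes the inheritance and dilution analyses testable against truth.

A focus is a 2D isotropic Gaussian (default sd 1.6 px) at one pole. Its
amplitude is *calibrated*, per cell, so that the ratio between the mean
intensity inside the focus region and the mean over the rest of the cell
equals the requested partition ratio. "Focus region" is defined by the
same convention the detector uses (masked blur, min–max normalization,
0.5 threshold); in the noise-free limit that region is independent of the
amplitude, so the calibration is a closed-form solve rather than an
iteration. The practical consequence: `detectFoci` + `partitionRatio`
round-trips the generator's ratio to better than 1% without noise, and the
tests hold it to a few percent with noise.

## Condensation coefficient

Per cell: subtract the median of all out-of-cell pixels, blur with a
Gaussian of sd 0.066 µm, min–max normalize within the cell
(`I_n = (I − I_min)/(I_max − I_min)`), and report the fraction of pixels
with `I_n` strictly below a threshold (0.3, 0.5, 0.7), scaled to percent.
Homogeneous cells sit near 50 because the midpoint of the min–max range
splits symmetric noise evenly; condensation skews pixels dim and drives
the value toward 100. The statistic is invariant under positive affine
intensity transforms (inherited from the normalization), which the
property tests exercise directly.

Two implementation choices deserve emphasis:

* **Masked blur.** The smoothing step is a normalized convolution
  restricted to the cell mask. Blurring a hard-edged synthetic cell
  against its dark surround would darken a ~2 px rim, and after min–max
  normalization that rim — not the biology — would dominate the
  coefficient. Real micrographs do not have hard edges (the PSF spreads
  signal beyond the segmentation mask), so the masked blur is the honest
  emulation of the real pipeline, not a convenience.
* **Degenerate cells.** A constant-intensity cell has no min–max scale; it
  is flagged and excluded with a reason, never silently zeroed.

Coefficients can be normalized to a fluorophore-only reference population
(`normalizeToReference`), mapping that reference to mean 1.

## Focus detection and its three filters

`detectFoci` binarizes the blurred, normalized cell at `I_n ≥ 0.5` and
filters connected components by area (≥ 4 px), eccentricity of the
equal-second-moment ellipse (≤ 0.9), and an intensity filter implemented
as a raw-contrast floor: component mean over rest-of-cell mean ≥ 1.3.
The contrast floor is what makes the filter triple meaningful: min–max
normalization stretches even pure noise to [0, 1], so *every* homogeneous
noisy cell contains a connected blob above any normalized threshold, and
only a raw-intensity criterion separates a real focus from the brightest
noise patch. All three values are configurable and logged; they are this
package's defaults, tuned for the synthetic fixtures and meant to be
re-examined on real data.

## Focus tracking

Time-lapse foci are detected by the scale-normalized
Laplacian-of-Gaussian filter at the scale matched to a 600 nm blob
(`sd = diameter/(2√2)`), with the response amplitude at each strict local
maximum reported as the spot quality. Quality thresholds are
fixture-dependent (the response is linear in blob amplitude — a property
under test); the values used by interactive tracking tools are not
portable across implementations and are treated as annotations only.

Linking minimizes total squared frame-to-frame displacement under a 3 px
gate (solved as a linear assignment problem with dummy nodes, via
`clue::solve_LSAP`), then closes gaps of up to 2 frames within 3 px.
Gap-closing candidates are merged in deterministic order (frame gap, then
distance, then track ids). Four trajectory filters follow: first-frame
presence, field-of-view exit, first-frame false positives (tracks shorter
than 2 detections), and growth/division compliance; each removal is
logged with its reason.

Lifespans are first-to-last detection times; tracks that persist to the
analysis horizon are censored — counted in the percent-dissolved
denominator but excluded from the mean lifespan. The discretization
consequence is worth knowing: an exponential lifespan measured on a
15-minute grid is reported with a half-frame floor bias, and excluding
single-frame tracks (filter iii) truncates the short tail; the tests
therefore compare tracked lifespans against the realized truth of the same
foci, where agreement is exact, rather than against the continuous-time
mean. Default analysis horizons are 10 h (division) and 7.25 h
(elongation).

## Single-molecule diffusion

Localization fits an isotropic 2D Gaussian with offset to an 11×11 patch
around each isolated candidate (crowded candidates within 5 px are both
discarded); integrated counts `2πAσ²` convert to photons via the camera
calibration. Trajectories are linked by per-frame-pair Hungarian
assignment with a hard step cap and no gap closing. MSD curves are
time-averaged over overlapping displacement pairs (overlapping pairs
use the data more efficiently than disjoint ones and only affect error
bars, not expectations), and only
trajectories with ≥ 6 displacements are fitted.

The diffusion model is the motion-blur-corrected linear law:

> MSD = (8/3)·D_app·τ + 4σ²

fitted by ordinary least squares over 40 ≤ τ ≤ 200 ms, with `D_app` from
the slope ×3/8, `σ` from the intercept, and an R² ≥ 0.7 acceptance gate.
A caveat this package documents rather than silently correcting: for a camera that
averages the true position over the whole frame, the blurred MSD at lag
*n* is `4DΔt(n − 1/3)` — the 8/3 factor is exact only at the first lag.
Fitting this model across lags 1–5 therefore overestimates D by a
factor approaching 3/2 on fully blurred, noise-free data. The sub-step
Brownian simulator is the oracle for both statements: the first-lag ratio
`MSD(Δt)/(DΔt)` reproduces 8/3 to better than 2%, and the 3/2 estimator
bias is asserted in the test suite. Relative quantities (slow/fast weight
fractions, condition comparisons) are unaffected; absolute D values carry
the bias by construction.

Per-trajectory `log₁₀ D_app` values are decomposed by a two-component
Gaussian mixture fitted by EM on the raw values (not on histogram bins) —
deterministic initialization at the 25th/75th percentiles, equal weights,
a common sd, and a monotone log-likelihood (asserted per iteration in the
tests). Components are reported slow-then-fast. Because a two-component
EM happily splits a unimodal sample into two overlapping halves, the fit
is compared by BIC against a single Gaussian and flagged `degenerate`
when one component suffices.

Localization heat maps scale each cell to a normalized frame (long and
short axes to [−1, 1]), bin, apply four-fold quadrant symmetrization, and
normalize to unit mass; round cells with no defined long axis are skipped
with a warning.

## Absolute concentrations and apparent c_sat

The photon-counting chain is: per-frame integrated background-corrected
cell intensity, averaged over the five brightest frames (robust to
photobleaching during acquisition); conversion to photons
(`counts × g / (EM_nominal × f)`); division by the single-molecule
brightness — the *mode* `(k−1)θ` of a maximum-likelihood Gamma fit to
per-molecule photon counts (moment matching as fallback; the mode is
undefined and flagged for shape ≤ 1); and division by Avogadro's number
times the spherocylinder volume `πr²(L − 2r) + (4/3)πr³`, with length and
width measured from the label mask by principal-axis pixel extents (+1 px
for the half-pixel border). The generator draws per-cell copy numbers
from a target concentration given each cell's volume, so the pipeline's
recovery of the population mean is an end-to-end test of every link in
that chain.

Cells classified by focus presence yield group means ± sd; the apparent
saturation-concentration range is reported as
`[no-focus mean − sd, focus mean + sd]`. That range rule is an
interpretation (flagged `interpreted` in the output) consistent with how
paired population statistics of this kind are typically summarized, not a
published formula. Significance uses a two-sided Welch t-test on
replicate means, never on pooled single cells.

## Two-channel chaperone patterns

Reference-channel foci are connected components above 30% of the image
maximum (area ≥ 4 px, eccentricity ≤ 0.75). Each centroid centers a
23×23 px ROI pair cut at identical coordinates in both channels and
normalized to the reference patch maximum; ROIs too close to a border are
discarded and counted. Averaged projections per channel are fit with an
anisotropic 2D Gaussian plus offset; FWHM is `2√(2 ln 2)` times the
geometric mean of the fitted sigmas (the geometric-mean convention is
recorded in the result object), and the classification statistic is
FWHM(probe)/FWHM(reference) with the probe's relative peak amplitude in
percent. A rosette (ring-shaped) probe is badly described by a single
Gaussian — by design the fit R² is reported and low values flagged
(`probe_fit_poor`) so a ratio > 1 from a rosette is interpreted with the
flag in view rather than trusted blindly. Profiles are taken along the
ROI center row; an option averages rows ±1.

## What the generator emulates — and what it does not

Emulated: spherocylindrical cell geometry with sub-pixel placement jitter;
uniform cytoplasmic signal plus calibrated polar foci; Poisson–EMCCD noise
with bias, read noise, EM and conversion gains; photobleaching decay;
dissolving foci with exponential lifespans; single division events with
configurable asymmetry; linear elongation; motion-blurred Brownian motion
via sub-frame position averaging (default 50 substeps); flat-field and
EM-gain calibration series; rosette/punctate/amorphous two-channel
patterns.

Not emulated: optical aberrations and 3D PSFs (foci and emitters are 2D
Gaussians); EM excess noise; pixel nonuniformity; phase-contrast imaging;
nucleoid structure; multi-generation microcolony growth (division mode
renders one division per lineage — enough for inheritance and
dilution-compliance analyses, not for lineage trees); molecular
photophysics beyond a single on–off bleaching model; cell segmentation
errors (masks are exact). Passing round-trip tests therefore demonstrates
the *estimators* are correct under the stated imaging model; they do not
certify performance under segmentation error or optical artifacts, which
real data will add.

## Numerical choices and scales

Convolutions use reflective (mirror-pad) boundaries. Assignment ties are
broken deterministically by index order. All randomness flows from seeds
recorded in the configuration objects, and identical seeds give
bit-identical outputs (asserted in the tests). The simulation scales used
by the test suite and the acceptance script — around 100–150 cells per
population statistic, 6-frame photobleaching movies, 40-frame time lapses,
2000–10000 Brownian tracks, 5000 photon samples, 128–192 px calibration
frames — were chosen as the smallest sizes at which the estimators'
sampling error is comfortably inside the documented recovery tolerances
for each fixture.

## Known limitations

* `D_app` carries the documented 3/2 motion-blur bias of the printed MSD
  model on fully blurred data.
* The focus-amplitude calibration assumes the default detection
  convention; detecting with a different threshold will read a slightly
  different partition ratio than requested.
* The lifespan estimator inherits frame-grid discretization and
  short-track truncation; compare against discretized truth, not
  continuous means.
* `segmentFallback` is a demonstration segmenter only.
* The c_sat range rule is an interpretation and flagged as such.
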