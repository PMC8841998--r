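---
title: "Quantifying a duplex PCT/CRP lateral flow assay: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a duplex PCT/CRP lateral flow assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaquant)
```

## The measurement problem

A duplex lateral flow strip carries three printed lines, 3 mm apart on a
4 mm-wide membrane: a CRP test line at the bottom, a PCT test line in the
middle, and a control line on top. A fluorescence reader excites
europium-labelled detection antibodies at 380 nm and images the emission
above 530 nm with a single-channel sensor that stores unprocessed raw
counts. Quantification means turning such an image into two
concentrations — PCT in ng/mL, CRP in mg/dL; the units differ on purpose,
reflecting the roughly thousandfold difference in physiological range,
and are carried explicitly through every record, with conversion refused
rather than implied.

Two features make this harder than reading a single test line. First,
all strips of a batch must be rendered at one brightness setting from the
raw data, otherwise camera auto-correction introduces background
disparity between strips that calibration cannot remove. Second, the CRP
response is not monotone: beyond about 1 mg/dL, excess unlabeled analyte
occupies the capture sites and the signal *falls* as concentration rises
(the high-dose hook), so one intensity maps to two candidate
concentrations.

## Forward models

The package's simulation module doubles as the definition of the assumed
signal chemistry:

* **PCT** — affine, `I = beta + alpha * c`, because the measured response
  is linear through 100 ng/mL. Defaults: `alpha = 120` intensity units
  per ng/mL, `beta = 200`.
* **CRP** — `I = alpha * (c/h) / (1 + (c/h)^2)`, the simplest unimodal
  single-parameter-apex curve through the origin, with maximum
  `alpha / 2` exactly at `c = h` (default `h` = 1 mg/dL, where the hook
  is observed; `alpha = 12000`). The form is symmetric on a log axis
  (`f(hx) = f(h/x)`), which is a modelling convenience, not a measured
  fact: the empirical pairing of equal-intensity concentrations (for
  example, 2.5 mg/dL reading like 0.05 mg/dL) is steeper than this
  symmetric pairing. None of the package's algorithms depend on the
  symmetry; only synthetic-truth experiments inherit it.

Replicate noise is multiplicative lognormal with unit mean, because
intra-assay variability of these assays is reported as a coefficient of
variation, which is scale-free. The default CVs are frozen at the
midpoints of the measured intra-assay ranges: calibration (buffer)
panels 8.9% for PCT and 9.4% for CRP; serum panels 9.1% and 7.1%. A
single serum matrix factor (0.85) scales serum signals relative to
buffer; a matrix difference is expected, its size is not documented, and
any fixed value exercises the matrix-specific calibration logic equally.

## What the synthetic images emulate — and what they do not

`render_strip()` produces a 16-bit single-channel raw image: a flat
blank level (300 counts) plus one Gaussian band per line whose
column-integrated amplitude *equals* the requested line intensity, an
optional linear background ramp, and optional Gaussian read noise. At
the default pixel pitch of 0.02 mm/px the 3 mm line spacing is 150 px
and the bands (sigma 8 px) sit comfortably inside the 500 x 1500 ROI.
The intensity scale (control 8000, CRP maximum 6000, PCT at
100 ng/mL 12200) was chosen once so that the default display gain of 60
puts the 8-bit render in mid grey without clipping.

Deliberately not modelled: membrane texture and flow fronts, cassette
misregistration and rotation, optical vignetting, Bayer mosaics (the
sensor is treated as monochrome), antibody lot effects, and any reaction
kinetics. Passing the round-trip tests therefore shows that the
*quantification chain is linear and offset-invariant on ideal bands*; it
does not certify performance on real membranes, which is what the
clinical method comparison is for.

## Image quantification choices

* **Brightness**: `out = clip(round(gain * raw * 255 / 65535), 0, 255)`.
  `quantify_batch()` accepts exactly one gain — mixed gains within a
  batch are an error, not a warning, because they are the background
  disparity the raw-data design exists to avoid. Past the gain where the
  brightest band pixel clips, the integrated area saturates; the tests
  pin this behaviour.
* **Profile**: unweighted channel mean (for RGB input), averaged across
  the ROI width, bottom row first. The profile baseline is a straight
  line least-squares fitted to the rows at or below the median grey — the
  bands occupy a minority of the ROI, so the lower half of the
  distribution is background. This removes offsets and linear
  illumination ramps exactly.
* **Line location**: local maximum within ±0.6 mm of the expected
  centre; a peak must clear both 3x the robust profile noise
  (1.4826 x MAD) and an absolute floor of 1 grey (the 8-bit quantisation
  step), otherwise the window falls back to the expected centre — the
  correct behaviour for a blank test line.
* **Integration**: fixed 1.2 mm window (60 px at default pitch) centred
  on the located peak, a local linear baseline through the means of the
  two 10-px flanking segments, then composite Simpson's 3/8 at unit row
  spacing. The window is symmetrically trimmed to the largest interval
  count divisible by 3 rather than patching the remainder with a
  different rule; with 60-px windows the trimmed mass is tail mass.
  Negative areas are floored at 0: intensity is physically non-negative.
* **Control validity**: `area_ctrl >= max(5 * noise_sd * window, 10)`
  grey·px. The absolute floor keeps a noiseless flat profile from
  validating itself.

## Calibration

The PCT curve is ordinary least squares on (concentration, mean
intensity). The CRP curve interpolates the calibrator means with a local
cubic of the Akima family on a **log10-concentration axis** — the
standard axis for a ladder spanning 2.3 decades, and the axis on which
the apex grid is laid out (10,001 log-spaced points).

Two Akima slope rules are implemented; the default is the
**modified-Akima ("makima") rule**, with the original 1970 weights
available as `method = "akima"` (cross-checked against
`pracma::akimaInterp` to machine precision in the tests). The modified
rule was chosen because it tempers the overshoot of the original rule
between unevenly spaced calibrators, which matters twice here: on
monotone stretches of the ladder the interpolant should stay monotone,
and near the hook it determines where the fitted maximum lands. A
noteworthy, honestly reported consequence: *no* Akima-family interpolant
through the default ladder `{0.05, 0.1, 0.25, 0.5, 1, 2.5, 5, 10}`
peaks exactly at the 1 mg/dL calibrator, because the node slope at an
asymmetrically flanked knot (0.5 below, 2.5 above) is nonzero. The
original rule puts the fitted apex at 0.935 mg/dL, the modified rule at
0.971 mg/dL. The package reports the apex as computed; the
3% displacement is an interpolation property, not a calibration error,
and shrinks as calibrators are placed log-symmetrically around the hook.

Other calibration decisions:

* **R² against replicates.** An interpolant reproduces its means by
  construction; its R² is only meaningful against replicate scatter, so
  both fitters accept replicate-level data and compute R² there.
* **Extrapolation.** Below the lowest knot the curve continues linearly
  through the origin — the signal is physically anchored at zero, and the
  1:10-diluted predictions of low-end candidates need this region. Above
  the highest knot the end slope continues on the log axis (used, with a
  flag, when a specimen lies beyond the ladder); evaluations floor at 0.
* **Inversion.** Linear curves invert in closed form (floored at 0,
  flagged when outside the calibrated range). Hooked curves are inverted
  by bracketed root-finding (`uniroot`, tolerance 1e-12 on log10
  concentration) on the ascending and descending branches separately;
  candidates reproduce the queried intensity to better than 1e-6 of its
  scale. An intensity above the fitted maximum by more than the
  tolerance is a no-solution error; within tolerance of the maximum it
  is degenerate at the apex.
* **LoD** is the blank mean + 3 SD mapped through the ascending branch —
  the standard analytical convention, adopted because no explicit
  criterion is documented for the platform.

## Hook resolution by serial dilution

A CRP specimen is measured neat (25 µL) and 1:10 diluted (2.5 µL
specimen + 22.5 µL buffer), 27.5 µL of specimen in total. `resolve()`
implements the decision rule:

1. invert the neat intensity into its branch candidates;
2. for each candidate `c`, predict the diluted intensity `f(c / D)`;
3. select the candidate with the smallest relative deviation from the
   observed diluted intensity, and report it **from the neat strip** —
   the dilution is a confirmation step, not the measurement.

Scoring uses relative deviation because the intensities span a decade.
The acceptance threshold `tau_accept = 0.35` must exceed plausible
replicate CVs (up to ~15%) while rejecting gross inconsistency; the
ambiguity margin `rho = 0.10` flags pairs whose two branch deviations
are too close to trust. Both are configurable.

One rule goes beyond the naive candidate inversion. Within
`apex_band = 5%` of the fitted maximum — including noisy readings
slightly *above* it, which at a 10% reading CV are common whenever the
truth is within ~±40% of the apex — the neat inversion is
ill-conditioned and its two candidates collapse towards the apex, where
the dilution can no longer separate them. The resolver instead takes the
branch candidates at the band-edge intensity `0.95 * max`, letting the
diluted strip decide between two genuinely distinct hypotheses; if even
then the deviations are indistinguishable, the apex itself is returned
with branch `"degenerate"`. Without this rule, near-apex pairs would
frequently collapse to degenerate results and the branch-selection power
of the protocol would fall well short of its measured ~99.9%.

A pair whose best deviation exceeds `tau_accept` is returned with an
`"inconsistent"` flag rather than an error (`strict = TRUE` restores the
error): in batch use, one bad strip pair should mark its own row, not
abort the run.

## Validation machinery

`select_calibrators()` sorts the panel by reference concentration,
splits it into `k` rank bins, and takes the *extreme* member of the two
endpoint bins plus one random member of each interior bin. The endpoint
rule is deliberate: a calibration set must bracket the range it will be
asked to invert (and the serum calibrators were selected to cover the
whole detection range); a fully random one-per-bin draw leaves the
expected log-range coverage near 78% and regularly strands test samples
outside the calibrated range.

`compare_methods()` reports both Pearson (with its two-sided p-value)
and Spearman coefficients — published comparisons quote either — plus the
regression of predicted on reference, the direction in which such
platforms are plotted against their gold standard. Out-of-range
exclusion (for example, reference PCT above the validated 100 ng/mL) is
an explicit, logged filter that keeps the excluded rows in the output
table; it is never silent.

`run_validation_experiment()` ties it together: exclude, select 5
calibrators, fit the matrix-specific curve on reference concentrations
versus triplicate-mean intensities, predict the remaining samples
(CRP through the resolver), compare, and stage PCT samples by the
clinical intervals: local infection (0.05–0.5], sepsis (0.5–2], severe
sepsis (2–10], septic shock (>10) ng/mL, right-closed.

The harness runs on intensity-space panels (`render = FALSE`): the
rendering-and-requantification stage is proven proportional to 2% and
offset-invariant by its own round-trip tests, so the repeated-seed Monte
Carlo does not re-render tens of thousands of strip images. Problem
sizes used throughout: 24-sample panels (5 calibrators + 19 test,
triplicates) over 200 seeds for correlation recovery; 1,000 noisy pairs
(CV 10%, truths outside ±20% of the apex) for branch-selection power;
10,001-point grids for apex location and 10^6-point scans as inversion
oracles.

Two limits of the noiseless "perfect recovery" intuition are worth
stating. For PCT the fitted line *is* the generating model, and the
noiseless round-trip is exact to machine precision. For CRP the
interpolant equals the generating model only at the calibrator knots, so
noiseless recovery between knots is bounded by interpolation error —
with 5 sparse calibrators the worst-case error can reach tens of
percent near the steep low end, shrinking to ~2% with 9 calibrators.
This is a property of interpolating calibration itself, and the reason
dense, range-covering calibrator sets matter.

## Known limitations

* The CRP hook form is a stand-in; its log-symmetric equal-intensity
  pairing differs from the empirically observed pairing, so simulated
  branch-resolution difficulty near the apex may differ from reality.
* The Akima apex of a sparse asymmetric ladder does not sit exactly on
  the peak calibrator (see above); apex-adjacent concentrations are the
  least identifiable region of the assay regardless of interpolant.
* Real-image effects (registration, vignetting, membrane noise) are out
  of scope of the simulator; the image pipeline is validated on ideal
  Gaussian bands plus ramps and read noise.
* The dilution protocol assumes the 1:10 companion is measured under the
  same gain and matrix; it consumes a second strip, and pairs whose
  readings disagree with both branches are flagged, not repaired.
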