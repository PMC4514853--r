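---
title: "Method dependence of DCE-MRI biomarkers: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Method dependence of DCE-MRI biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcegrid)
```

`dcegrid` exists to answer a methodological question: how much do the
absolute values and the test–retest repeatability of DCE-MRI kinetic
parameters depend on the analysis pipeline, holding the data fixed?  The
package therefore implements a full 2×2×2 grid of analysis options —
compartment model (2- vs 3-parameter), vascular input function (individual
vs population) and ROI treatment (whole-ROI vs pixel-by-pixel) — plus the
repeatability statistics to compare them, and a synthetic study generator
whose structure matches the assumptions of the analysis so that every claim
the package makes can be verified end to end.

## The kinetic models and their assumptions

Both models describe the tissue contrast-agent concentration, measured here
as signal change from baseline (ΔSI), as a function of the plasma curve
$C_p(t)$:

$$C_t(t) = v_p\,C_p(t) + K^{trans}\int_0^t C_p(u)\,
  e^{-k_{ep}(t-u)}\,du, \qquad k_{ep} = K^{trans}/v_e,$$

with $v_p \equiv 0$ in the 2-parameter (standard Tofts/Kety) variant.  The
assumptions inherited from this family are the usual ones: well-mixed
compartments, fast water exchange, no bolus dispersion or arrival-delay
fitting (the plasma curve is defined to be zero before the injection frame),
and a linear relationship between ΔSI and concentration.  The package
deliberately works in ΔSI units throughout, with no T1 mapping or
signal-equation correction: both tissue and plasma curves are in the same
arbitrary units, so the fitted parameters are interpretable in the usual
min⁻¹/fraction units as long as that proportionality holds equally for both.

Unit conventions: `Ktrans` and `kep` are in min⁻¹; curve time axes are in
seconds from injection; biexponential VIF clearance rates are stored in s⁻¹
(the scale on which population VIFs are conventionally printed) and
converted by ×60 at the model boundary.  `kep` is never a free quantity —
every parameter container derives it as `Ktrans/ve`, so the identity holds
to machine precision in any fit output.

## Evaluating the convolution

Two evaluation paths are provided, and they cross-check each other in the
test suite:

- **Closed form** (`convolve_biexp_closed_form`), used whenever the VIF
  carries biexponential parameters:
  $K^{trans}\sum_i A_i\,(e^{-m_i t} - e^{-k_{ep} t})/(k_{ep} - m_i)$.
  When $k_{ep}$ approaches a clearance rate the difference quotient is
  evaluated through a numerically stable `expm1` form, and below
  $|(k_{ep}-m_i)\,t| < 10^{-8}$ it switches to the confluent limit
  $K^{trans} A_i\,t\,e^{-k_{ep} t}$ (with its first-order correction), which
  is exact to double precision at that threshold.
- **Segment-exact numerical convolution** (`convolve_numeric`), used for
  sampled (individual) VIFs: the sampled curve is treated as piecewise
  linear and each segment's integral against the exponential kernel is taken
  in closed form, accumulated with cumulative sums (with a sequential
  recursion fallback when $k_{ep}\,t_{max}$ is large enough that the
  rescaled exponentials could overflow).  The only discretisation error is
  therefore the piecewise-linear representation of $C_p$, $O(h^2)$ in the
  sampling step.  By default the sampled curve is first interpolated onto an
  8× finer grid with a cubic spline, reducing the representation error of a
  smooth VIF to $O(h^4)$; at the 6.4 s acquisition spacing this brings the
  disagreement with the closed form from ~1×10⁻³ to ~3×10⁻⁵ of the curve
  maximum, and on a 0.01 s grid the two paths agree to better than 10⁻⁶
  without refinement.  `refine = 1` disables the spline for impulse-like or
  already-dense curves, where spline overshoot would be a concern.

## Fitting, filtering and aggregation

Fits are bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`)
over all frames, including the pre-injection frames where the model
predicts zero — keeping them anchors the baseline.  Defaults that matter:

- **Bounds** (`pk_bounds`): `Ktrans` ∈ (10⁻⁵, 10] min⁻¹, `ve` ∈ (10⁻⁵, 1],
  `vp` ∈ [0, 1).  These are positive-definite physiologic limits; a fit that
  fails to converge or lands at an open endpoint is flagged invalid and all
  its parameters set to NaN, and such pixels are excluded from every
  summary rather than propagated.
- **Initialisation**: `Ktrans` 0.1 min⁻¹, `ve` 0.2, `vp` 0.02 — near typical
  tumour medians.  Whole-ROI fits use 3 starts (Ktrans scaled ×1, ×1/3, ×3)
  because a single ROI-average curve deserves the robustness; pixel fits use
  a single start because cost scales with the pixel count and the curves are
  individually noisier than any local-minimum structure.
- **Enhancement filter**: a pixel enters the fit only if its peak
  post-injection ΔSI reaches at least 50% of its baseline SI (inclusive at
  the boundary); non-positive baselines are excluded under a distinct
  reason code.  Exclusion and NaN counts are carried in every pixel-mode
  result.
- **Slice selection**: the three analysed slices are those with the largest
  ROI area, ties broken toward the centre of the tumour extent.  The
  per-slice results are averaged arithmetically, parameter by parameter.
  Because `kep` is averaged (and, in pixel mode, medianed) per slice like
  any other parameter, the aggregate `kep` is intentionally *not* equal to
  aggregate `Ktrans` / aggregate `ve`; the identity holds at the level of
  individual fits, where it is structural.
- **Pixel summaries** use the median over valid pixels, which is robust to
  the long right tail of pixel-level fits; NaN pixels are removed before
  the median, not propagated.

## VIF construction

Individual VIFs are extracted from a user-supplied vessel mask: voxels are
kept when their post-injection peak ΔSI is at or above the 75th percentile
of in-mask peaks, strictly positive, and occurs within the first 5
post-injection frames (a bolus passes early; late-peaking voxels are
partial-volume tissue).  Both thresholds are arguments, since automated
vessel-voxel selection has no canonical published rule; an empty selection
is an explicit error rather than a silent fall-back to the mask mean.

The population VIF is the unweighted pointwise mean of all individual
curves (all subjects and visits) on their common post-injection grid,
fitted to $A_1 e^{-m_1 t} + A_2 e^{-m_2 t}$ by bounded least squares.
Sum-of-exponentials fitting is notoriously multi-modal, so the fit uses
three deterministic starts with fast rates log-spaced over 0.1–0.01 s⁻¹
(slow rate a fixed 1/30 of the fast), amplitudes seeded by linear least
squares given the starting rates; amplitudes are bounded below at zero, so
a negative component is impossible by construction.  The fitted curve, not
the raw mean, is what downstream fitting consumes, and the parameters are
stored fast-component-first.

## The synthetic study generator

`generate_study` emulates a 12-subject × 3-visit test–retest experiment:
50 frames at 6.4 s (320 s), injection after 10 baseline frames with the
baseline averaged over frames 5–10, an 8-slice volume with the tumour in
the central 3 slices, and a small vessel region carrying the plasma curve.
Parameters are drawn hierarchically on the log scale — subject level
(between-subject SD), then visit level (day-to-day SD), then optionally a
smoothed lognormal within-tumour field — and tissue ΔSI follows the
3-parameter model driven by a biexponential plasma curve with amplitudes
0.64/0.42 ΔSI and clearance rates 0.0333/0.0010 s⁻¹.  Defaults:
population medians `Ktrans` 0.11 min⁻¹, `ve` 0.21, `vp` 0.03; log-SDs
(inter, intra) of (0.22, 0.33) for `Ktrans`, (0.10, 0.15) for `ve`,
(0.38, 0.46) for `vp`, chosen to sit on the scale of variance components
reported in small-animal test–retest work and implying day-to-day wCVs of
roughly 39%, 16% and 58% respectively.  Additive Gaussian SI noise
(default SD 0.004) approximates the high-SNR regime; a Rician model would
matter near zero signal and is deliberately out of scope.  Baseline SI
levels (tumour 0.06, vessel 0.25, background 0.04) are set so typical
tumours enhance by ~100–150% of baseline — comfortably past the 50% filter
— while genuinely hypo-enhancing draws can still fail it, so exclusion
paths are exercised.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: MR signal-equation nonlinearity and T1 effects,
motion and registration error across visits, inflow and partial-volume
artifacts in the vessel, bolus dispersion and arrival-time variation, and
Rician noise floors.  Tests on generated data validate the estimators under
the model's own assumptions; they cannot certify accuracy when those
assumptions fail.

## Repeatability statistics

All statistics operate on natural logs (the parameters are right-skewed and
multiplicative; the wCV is invariant to the log base provided the
back-transform matches).  The within-subject CV is the Bland–Altman
log-method estimator: per-subject deviations from the subject's own mean
are pooled with $\sum_i (k_i - 1)$ degrees of freedom, and
$\mathrm{wCV} = e^{s_w} - 1$.  Its 95% bounds use the chi-square interval
for the pooled variance — the interval method is recorded in the result
object since other choices exist.  Note a small-sample property verified in
the test suite: with 12 subjects × 3 visits (24 df), $E[s_w]$ is slightly
below $\sigma_w$ (chi-distribution bias), so the mean estimated wCV at
$\sigma_w = 0.3$ sits near 34.6% rather than the asymptotic
$e^{0.3}-1 = 35.0\%$; the calibration test allows for this known bias.

Variance components use the one-way method-of-moments (ANOVA) estimator
with the unbalanced-design coefficient $k_0$, truncating the
between-subject component at zero — that truncation is what produces the
"0.000" entries conventional in published tables.  Method comparisons are
paired log-scale t tests with Bonferroni adjustment over the supplied
family; this is a deliberate simplification of the mixed-model machinery
sometimes used for the same purpose, exact for the balanced paired grid the
pipeline produces and transparent about what is being tested.  With 13
contrasts the per-comparison cutoff at overall α = 0.05 is
0.05/13 ≈ 0.0038, so a raw p of 0.004 is declared non-significant.

In grid summaries, the median and IQR of a parameter are taken over
subjects after averaging each subject's days (so n equals the number of
subjects), while the wCV consumes the per-day values; both choices are
arguments of record rather than hidden behaviour.

## Problem sizes and determinism

The test suite runs the full pipeline at reduced but structurally faithful
sizes: a 20×20×8 volume with ~180 tumour voxels for the 12×3 noiseless
recovery check, 3-subject studies for the 8-combo grid runs, 100 parameter
draws for the convolution agreement property, and 1000-replicate
simulations for the wCV and variance-component calibrations.  These sizes
were chosen so the whole suite completes in well under a minute while
keeping every Monte-Carlo check's standard error far below its tolerance.
All randomness flows through explicit seeds; the generator and the pipeline
are bit-reproducible for a fixed seed, and the multi-start optimisers use
deterministic start grids rather than random restarts.

## Known limitations

- ΔSI as a concentration surrogate ties parameter units to acquisition
  settings; absolute comparability across scanners would require
  signal-to-concentration conversion, which is intentionally out of scope.
- The individual-VIF selection rule is a reasonable default, not a
  published standard; its thresholds are exposed and logged.
- Whole-ROI fits of heterogeneous tumours estimate parameters of the mean
  curve, which is not the mean of the parameters — this is a feature under
  study (it is one of the method effects), not a defect, but it means
  "truth" comparisons on heterogeneous phantoms are only meaningful at the
  pixel level.
- No motion correction or cross-visit registration: series are assumed
  aligned, as in the cradle-immobilised acquisition the generator emulates.
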