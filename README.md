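# dcegrid

Quantitative DCE-MRI biomarkers — the transfer constant K<sup>trans</sup>,
the reflux rate k<sub>ep</sub>, the extravascular extracellular volume
fraction v<sub>e</sub> and the plasma volume fraction v<sub>p</sub> — are
reported in absolute units, yet their values depend strongly on analysis
choices that vary between centres: which compartment model is fitted, where
the vascular input function (VIF) comes from, and whether fitting happens on
a whole-ROI average curve or pixel by pixel. `dcegrid` implements that full
2×2×2 analysis grid together with the test–retest statistics needed to
quantify how each choice shifts both the absolute parameter values and their
repeatability, plus a synthetic 4D study generator so the whole experiment
can be reproduced at desk scale.  It is aimed at imaging scientists who run
or audit quantitative DCE-MRI pipelines, preclinical or clinical.

## The models and statistics

Tissue contrast-agent concentration is measured as signal change from
baseline, ΔSI(t) = SI(t) − SI(baseline), with the baseline averaged over
steady-state pre-contrast frames.  Two standard compartment models are
fitted against a plasma curve C<sub>p</sub>(t) (also in ΔSI units):

- **2-parameter (standard Tofts / Kety):**
  C<sub>t</sub>(t) = K<sup>trans</sup> ∫₀ᵗ C<sub>p</sub>(u) e^(−k<sub>ep</sub>(t−u)) du,
  with k<sub>ep</sub> = K<sup>trans</sup>/v<sub>e</sub>.
- **3-parameter (extended Tofts / General Kinetic):** adds the
  intravascular term v<sub>p</sub> C<sub>p</sub>(t).

The VIF is either *individual* (mean curve of automatically selected voxels
inside a vessel mask) or *population* (individual VIFs from all subjects and
visits averaged and fitted to a biexponential
C<sub>p</sub>(t) = A₁e^(−m₁t) + A₂e^(−m₂t)).  For a biexponential VIF the
convolution is evaluated in closed form,
K<sup>trans</sup> Σᵢ Aᵢ (e^(−mᵢt) − e^(−k<sub>ep</sub>t))/(k<sub>ep</sub> − mᵢ);
for sampled VIFs a segment-exact numerical convolution is used.  Fits are
bounded Levenberg–Marquardt least squares with positive-definite limits;
pixels enhancing less than 50% over baseline are excluded, and fits pinned
at a bound are flagged NaN and dropped from summaries, whole-ROI mode fits
the ROI-mean curve per slice and pixel mode summarises valid pixels by their
median, with the three analysed slices averaged either way.

Repeatability is quantified by the within-subject coefficient of variation
(Bland–Altman log method: pooled within-subject SD of the natural-log
values, back-transformed, minus one) with chi-square confidence bounds, and
by one-way method-of-moments variance components (inter- vs intra-subject,
log scale, truncated at zero).  Method contrasts are paired log-scale t
tests with Bonferroni adjustment.

## Worked example

Simulate a 4-subject, 3-visit study with the default acquisition (50 frames
at 6.4 s, injection after 10 baseline frames), run all 8 method
combinations, and summarise:

```r
library(dcegrid)

st  <- generate_study(study_design(n_subjects = 4, n_visits = 3),
                      truth_config(), seed = 7)
res <- run_grid(st)
attr(res, "population_vif")
#>          A1          m1          A2          m2
#> 0.641358836 0.033642964 0.422424408 0.001016305

s <- summarize_grid(res)
subset(s, parameter == "Ktrans")[, c("method_combo", "median", "wcv")]
#>    method_combo median  wcv
#>    2p.pop.whole  0.191 24.6
#>    3p.pop.whole  0.117 31.2
#>  2p.indiv.whole  0.192 24.6
#>  3p.indiv.whole  0.117 30.9
#>    2p.pop.pixel  0.193 24.6
#>    3p.pop.pixel  0.117 31.6
#>  2p.indiv.pixel  0.193 24.6
#>  3p.indiv.pixel  0.117 31.3
```

The population VIF refit from the noisy synthetic vessel curves lands on the
generator's biexponential (A₁ = 0.64, m₁ = 0.0333 s⁻¹, A₂ = 0.42,
m₂ = 0.0010 s⁻¹), and the summary shows the expected method dependence: the
2-parameter model absorbs the vascular term and reports a markedly higher
median K<sup>trans</sup> than the 3-parameter model on the same data — the
central reason absolute DCE-MRI values are not comparable across pipelines
unless the analysis is standardised.  `wcv` is the within-subject CV in
percent; `summarize_grid` also returns its confidence bounds and the
inter/intra variance components.

## Layout

- `R/` — forward models and convolutions, VIF construction, ROI/pixel
  fitting, repeatability statistics, the study generator, the grid pipeline,
  NIfTI/CSV/YAML I/O.
- `tests/testthat/` — unit, property and end-to-end suites with independent
  oracles (adaptive quadrature, dense-grid trapezoids, brute-force
  statistics).
- `vignettes/method-dependence.Rmd` — the methods vignette: model
  assumptions, numerical choices, generator design and limitations.
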