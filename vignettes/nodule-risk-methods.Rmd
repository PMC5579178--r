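---
title: "Methods: scoring systems, size definitions and the comparison pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring systems, size definitions and the comparison pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulerisk)
```

## The problem

In low-dose CT lung cancer screening, most detected pulmonary nodules are
benign; nodule management protocols decide who gets annual screening, a
short-interval follow-up CT, or immediate work-up. Three widely used
strategies take different approaches:

* the **PanCan (Brock) model** — a logistic regression on subject and
  nodule covariates producing a continuous malignancy-risk index
  (percent), with four published management categories;
* **ACR Lung-RADS v1.0** — five ordinal categories (1, 2, 3, 4A, 4B)
  driven by nodule type and size;
* **NCCN guidelines v1.2016** — six ordinal categories driven by nodule
  type and size.

The systems also *define nodule size differently*: the PanCan model uses
the longest axial diameter (`longest_c`), Lung-RADS an "average diameter"
that we realize as the volumetric mean diameter from segmentation
(`mean3d`), and NCCN the mean of the longest and perpendicular axial
diameters (`mean_axial`). This package scores nodules under any
system × size-definition combination and compares discrimination
(malignant vs. benign) at the participant level with paired DeLong tests,
so both the systems themselves and their sensitivity to the size
definition can be studied.

Baseline information only is used throughout: growth-based branches of
Lung-RADS and NCCN, the subjective Lung-RADS 4X upgrade, and NCCN's
multiple-ground-glass-nodule rules are deliberately out of scope, which
restricts what the categorical systems can express but makes the three
systems comparable on single-time-point data.

## Scoring rules

**PanCan.** The risk index is `100 · logistic(β₀ + Σ βᵢxᵢ)` with
covariates age (centred at 62 years), female sex, family history of lung
cancer, emphysema, nodule type (part-solid / non-solid vs. solid), upper
lobe location, nodule count on the scan (centred at 4), spiculation, and
transformed size `(d/10)^(-1/2) − 1.5811` (centred at a 4 mm nodule).
Coefficients are configuration, not code: the bundled default
(`inst/extdata/pancan_model2b.json`) carries the published full model with
spiculation from McWilliams et al. (2013), and any alternative set can be
supplied as JSON/YAML. Nodules with benign-pattern (complete, central,
popcorn, concentric-ring) calcification and perifissural nodules fall
outside the model's derivation population and are assigned exactly 0%.
Category cutpoints 1.5 / 6 / 30 (percent) are left-closed.

**Lung-RADS v1.0 (baseline branches).** Diameters are rounded to the
nearest whole millimetre before threshold tests; halves round up — an
assumption, but the only convention consistent with every published
worked example we reproduce (e.g. an 8.5 mm volumetric mean diameter
behaves as 9 mm). Solid: `<6` → 2, `6–7` → 3, `8–14` → 4A, `≥15` → 4B.
Part-solid: solid component `≥8` → 4B; total `≥6` → 4A if the solid
component is `≥6`, else 3; total `<6` → 2. Pure ground-glass: `<20` → 2,
`≥20` → 3. Benign-pattern calcification → 1.

**NCCN v1.2016.** No rounding. Solid and part-solid nodules are
categorized by *total* diameter (`<6` → 1, `[6,8]` → 5, `>8` → 6; the
6–8 mm band is read as a closed interval, consistent with a published
6.1 mm example mapping to category 5). Pure ground-glass: `≤5` → 2,
`(5,10]` → 3, `>10` → 4. The guideline states no calcification rule;
benign-pattern calcification is mapped to category 1, paralleling
Lung-RADS category 1 and the PanCan 0% convention — a documented choice,
not a guideline quotation. Perifissural nodules, mentioned by neither
categorical system, are scored as solid nodules of their size in both;
only the PanCan model forces them to 0%.

Within each system a numeric *rank* orders management intensity
(PanCan: the risk index itself; Lung-RADS: 1,2,3,4A,4B → 1..5; NCCN: the
numeric category). Ranks are never compared across systems.

## Participant-level analysis

Per participant and per system × size definition, the nodule with the
maximal rank is the *risk-dominant* nodule; ties are broken uniformly at
random from a seeded stream, so runs are reproducible from one integer
seed (the seed fans out to named substreams, so cohort generation and
tie-breaking are independently reproducible). The participant's label is
their cancer status — a cancer participant whose dominant pick happens to
be a benign nodule remains a positive with that nodule's score, matching
a person-level clinical reading and introducing the same selection bias
toward large benign nodules as the original design.

Discrimination is summarized by the midrank (Mann–Whitney) AUC; the
empirical ROC curve is built over every distinct threshold and its
trapezoidal area equals the midrank AUC exactly, ties counting ½.
Pairs of systems on the same participants are compared with the DeLong
test for correlated ROC curves (structural components with midranks;
two-sided normal p). Within a family of three comparisons the Bonferroni
threshold is `0.05/3 ≈ 0.0167`. `compare_systems()` runs an
"as-published" row (each system under its own definition) plus one row
per uniform definition, and additionally compares definitions within each
system.

The demographics table mirrors the usual cohort-characteristics layout
over the union of risk-dominant nodules: chi-square tests without
continuity correction for categorical rows, Welch unequal-variance
t-tests for continuous rows (both unstated in common practice; these are
documented choices, and our tests assert bounds rather than exact printed
p-values). When a continuous row is constant in both groups the test is
undefined and reported as `NA`.

## The synthetic cohort generator

Screening-trial data cannot be redistributed, so `simulate_cohort()`
generates cohorts with the published case-control structure: 613
participants by default, cancer prevalence 64/613, one malignant nodule
per cancer participant, and Poisson numbers of additional benign nodules
(mean 0.3 for cancer participants, 0.5 otherwise, capped at 5).

The size model is the load-bearing design choice. Each nodule has a
latent "true" size `s`, log-normal within its malignancy group, and the
three size definitions observe `s` with definition-specific noise:

* `d_mean3d = s·c`, compactness `c ∈ (0.85, 1]` — least noisy, standing
  in for measurement from the full 3D extent;
* `d_longest = s·e`, elongation `e = exp(Exponential(5)) ≥ 1` — noisiest:
  an elongated or irregular nodule overestimates size along one axis;
* `d_perp = s·u`, `u ∈ (0.75, 1]`, so the mean axial diameter
  `s(u+e)/2` is intermediate.

This encodes the measurement hierarchy the comparison is designed to
expose (volumetric mean best, longest axial diameter worst) and
guarantees `d_perp ≤ d_longest` and `d_mean3d ≤ d_longest` by
construction. An alternative we rejected — drawing `d_longest` as the
base quantity and deriving the mean diameters from it with multiplicative
noise — makes the volumetric diameter the *noisiest* definition, which
inverts the documented direction of the size-definition effect and
contradicts how these measurements arise physically.

The latent medians and spreads are calibrated numerically (the median of
`log s + Exp(5)` has no closed form) so the *observed* longest-diameter
distributions match the published risk-dominant nodule groups: benign
median 6.1 mm / mean 7.6 mm, malignant median 13.9 mm / mean 16.5 mm,
with the right-skewed upper tail those means imply. The implied median
ratios `mean3d/longest ≈ 0.80` and `mean_axial/longest ≈ 0.88` agree with
the published per-definition medians (4.9/6.1 and 5.4/6.1) without
further tuning. Type mix (solid/part-solid/non-solid 87/3/10% benign,
66/23/11% malignant), spiculation (1% vs 28%), benign-pattern
calcification (14% vs 0), perifissural fraction (8% of benign, always
solid, never malignant), upper-lobe fraction, and demographics (age, sex,
family history 16% vs 27%, emphysema) follow the published marginals;
those marginals describe risk-dominant nodules but are applied to all
generated nodules, a simplification that leaves the dominant-nodule
subset slightly closer to the targets than the full set. Covariates are
generated independently given cancer status (correlations such as
emphysema × age are unreported and not modelled). Part-solid solid
components are a uniform fraction (0.35–0.9) of every whole-nodule
measure.

What passing tests on these cohorts show — and do not show: they verify
the pipeline end-to-end and the *direction* of the published effects
(the continuous multivariable model outperforms both categorical
systems; NCCN is better under the volumetric mean than under the longest
diameter) across 100 seeded 613-participant replicates. They do not
reproduce the original AUC values (0.874/0.813/0.836): those depend on
the real data's covariate correlations and measurement errors, which no
generator of this kind can certify.

## Numerical choices

* Diameters are kept at full precision everywhere; rounding is a property
  of Lung-RADS alone.
* Volume → diameter uses the volume-equivalent sphere,
  `d = (6V/π)^{1/3}`; whether the original volumetric "mean diameter" was
  exactly this or a mean of three axis lengths is not pinned down, so the
  sphere-equivalent convention is implemented and documented. If both
  volume and `d_mean3d` are supplied they must agree within 1% relative
  tolerance; beyond that the row is rejected rather than silently
  preferred.
* Part-solid nodules missing solid-component measurements are rejected,
  not imputed.
* DeLong with zero estimated variance of the AUC difference: equal AUCs
  give `p = 1`; unequal AUCs raise a numerical error.
* Cohort files are written with `%.17g` precision so
  `read_cohort(write_cohort(x))` is exact and repeated writes are
  byte-identical.
* Test-suite problem sizes: the oracle-agreement checks use 500 random
  small ROC instances against brute-force pair counting, and 20 paired
  instances of n = 250 (100 cases) against a studentized sign-flip
  permutation oracle with 10⁵ resamples. Instances for the permutation
  comparison are sized inside the normal approximation's working regime,
  because the check targets the correctness of the covariance
  implementation: at much smaller n the DeLong p itself deviates from any
  exact resampling reference by more than resampling noise, which is a
  property of the approximation, not of an implementation. Generator
  calibration is checked on a cohort of ~5000 nodules; the directional
  properties on 100 replicates of 613 participants.

## Known limitations

* Baseline-only: no growth categories, no Lung-RADS 4X, no NCCN
  multiple-GGN handling, no NCCN v1.2017.
* The PanCan coefficients are external configuration; the bundled set is
  the published one but any validation against printed per-nodule risk
  indices is limited to band plausibility since the underlying subject
  covariates are not published.
* Synthetic cohorts share none of the real data's inter-covariate
  correlations; absolute AUCs from simulations should not be quoted as
  estimates of the systems' real-world performance.
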