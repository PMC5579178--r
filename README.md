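# nodulerisk

Risk stratification of screen-detected pulmonary nodules, and head-to-head
comparison of the systems that do it.

In low-dose CT lung cancer screening, nodule management protocols decide
which participants return for annual screening and which get short-interval
CT or immediate work-up. This package implements three widely used
strategies and the statistics to compare them on the same cohort:

* **PanCan (Brock) model** — logistic malignancy-risk index
  `p = logit⁻¹(β₀ + Σ βᵢxᵢ)` on age, sex, family history, emphysema,
  nodule type, upper-lobe location, nodule count, spiculation and
  transformed size `(d/10)^(-1/2) − 1.5811`; coefficients are supplied as
  configuration (the bundled default is the published full model with
  spiculation); benign-pattern-calcified and perifissural nodules are
  assigned 0%. Four categories at 1.5 / 6 / 30 %.
* **ACR Lung-RADS v1.0** — categories 1, 2, 3, 4A, 4B from nodule type
  and whole-millimetre-rounded size (baseline branches only).
* **NCCN v1.2016** — categories 1–6 from nodule type and unrounded size
  (baseline branches only).

Each system runs under any of three interchangeable nodule size
definitions — longest axial diameter (`longest_c`), volumetric mean
(volume-equivalent-sphere) diameter (`mean3d`), mean of longest and
perpendicular axial diameters (`mean_axial`) — so the sensitivity of each
system to the size definition can be quantified. The analysis pipeline
selects each participant's *risk-dominant* nodule per system (maximal
rank, seeded random tie-breaking), computes participant-level midrank
ROC/AUC, and compares systems and size definitions with paired DeLong
tests at a Bonferroni-corrected threshold (0.05/3 ≈ 0.0167). A calibrated
synthetic cohort generator stands in for screening-trial data, which
cannot be redistributed.

## Worked example

```r
library(nodulerisk)

coh <- simulate_cohort(n_participants = 613, seed = 20)
coh
#> nodule_cohort: 613 participants (66 with cancer), 891 nodules (66 malignant)
#>   type: solid 759, part-solid 45, ground-glass 87
#>   median d_longest_axial: 6.9 mm (malignant 14.9, benign 6.5)

cmp <- compare_systems(coh, seed = 20)
cmp$auc
#>          defn    pancan lung_rads      nccn
#>  as_published 0.843     0.751     0.709
#>     longest_c 0.843     0.734     0.703
#>        mean3d 0.855     0.751     0.727
#>    mean_axial 0.851     0.751     0.709
```

Each row is one choice of size definition (`as_published` = every system
under its own published definition); each cell is the participant-level
AUC for discriminating cancer participants from the rest using that
system's risk-dominant nodule score. On this synthetic cohort the
continuous multivariable model clearly outranks both categorical systems
(pairwise DeLong p < 0.0167 in every row of `cmp$pairwise`), every system
does best under the volumetric mean diameter and worst under the longest
axial diameter, and `cmp$defn_pairwise` shows the size-definition effect.
Absolute AUCs are properties of the generator, not estimates of
real-world performance.

Per-nodule scoring and the demographics table:

```r
head(score_cohort(coh, "nccn"))         # nodule_id, category_label, rank, ...
demographics_table(coh, seed = 20)      # malignant vs benign dominant nodules
plot(cmp, defn = "mean3d")              # ROC curves + category operating points
```

A thin CLI wraps the same functions
(`system.file("exec", "nodulerisk", package = "nodulerisk")`):

```sh
nodulerisk simulate --out cohort.csv --n 613 --seed 20
nodulerisk score    --input cohort.csv --system lung_rads --out scores.csv
nodulerisk report   --input cohort.csv --out-dir report/ --seed 20
```

See `vignettes/nodule-risk-methods.Rmd` for the scoring rules, the
generator's calibration and the statistical conventions.

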