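# tmtstroke

Analysis pipeline for studying how sarcopenia — proxied by low **temporal
muscle thickness (TMT)** on routine brain MRI — relates to outcomes after
acute ischaemic stroke in elderly patients, and through which mechanisms.

The package implements, as reusable and tested functions:

* **Outcome derivation** from raw registry records under fixed clinical
  rules: dysphagia (Functional Oral Intake Scale 1–6), early neurological
  deterioration (END: total NIHSS increment ≥ 2, consciousness subscore
  increment ≥ 1, motor subscore increment ≥ 1, or a new deficit, within
  3 weeks, measured against the running minimum of preceding exams; END₄
  is total increment ≥ 4), three period-specific recovery flags with
  eligibility exclusions, and a priori dichotomization of TMT at the
  cohort 25th percentile (low TMT = strictly below the cutoff).
* **Effect estimation**: 2×2 odds ratios with Woolf confidence intervals,
  `exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`; multivariable logistic
  regression by IRLS, either maximum likelihood or **Firth-penalized**
  (score modified by the hat-diagonal correction,
  `U*_j = Σ_i {y_i − π_i + h_i(½ − π_i)} x_ij`), with automatic fallback
  to Firth under rare events or separation; effect-modification scans
  with Wald p-for-interaction on product terms.
* **Mediation**: counterfactual natural direct/indirect effects of low
  TMT on poor outcome (mRS ≥ 3 at 3 months) through parallel binary
  mediators, on the risk-difference scale, with Monte-Carlo integration
  and a percentile bootstrap.
* **ROI-wise brain mapping**: priority merge of overlapping atlases
  (brainstem > AAL-like > JHU-like), per-ROI lesion burden as % of brain
  volume, one interaction model per ROI (burden + exposure +
  burden×exposure + covariates without total infarct volume), and
  pre-planned left/right symmetric pooling.
* **A synthetic cohort generator** that reproduces the registry's
  baseline marginals and plants known log-odds effects, serial NIHSS
  trajectories with injectable END events, consistent mRS trajectories,
  and contiguous toy lesion blobs with labelled toy atlases — so every
  stage of the pipeline is testable without any patient data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated registry-scale cohort and write tables under `results/`.
Condensed, the core steps are:

```r
library(tmtstroke)

# published outcome tables -> crude effects
tab <- table_fixtures()$dysphagia          # counts 55/96 vs 90/359
odds_ratio_2x2(tab$a, tab$b, tab$c, tab$d)
#> OR 2.29 (95% CI 1.53-3.42), p = 6.09e-05

# simulate, derive, estimate
cfg <- sim_config(600, seed = 20260922)
sim <- simulate_cohort(cfg)
dat <- analysis_table(sim$cohort, sim$nihss)
attr(dat, "cutoff_tmt")$value              # 5.25 mm; 150/600 below it
adjusted_effect(dat, "low_tmt", "end")
#> OR 2.24 (95% CI 1.34-3.75), p = 0.00182  [Firth]
```

The first call reproduces a published univariable odds ratio exactly
from its printed 2×2 counts. The second recovers the planted adjusted
END effect (true OR 2.75) within its confidence interval on one
simulated cohort of the registry's size; `analysis/03_effects.R` prints
the full nine-outcome table. `analysis/04_mediation.R` then decomposes
the low-TMT effect on poor 3-month outcome — on the same seed it admits
all three mediators and reports

```
  total effect:     +0.2371 (+0.1213, +0.3422)
  indirect (all):   +0.1193 (+0.0563, +0.1818)
  proportion mediated: 50.3% (28.1%, 80.5%)
```

on the risk-difference scale (planted structure: direct OR 1.8 plus
dysphagia/END/post-discharge-recovery channels).
`analysis/05_brain_mapping.R` shows the mapping stage flagging a pooled
bilateral cerebellar lesion-by-TMT interaction that the per-side models
mostly miss, and flagging nothing under the null.

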