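---
title: "Methods: sarcopenia, temporal muscle thickness and stroke outcomes"
author: "tmtstroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sarcopenia, temporal muscle thickness and stroke outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtstroke)
```

## The scientific problem

Sarcopenia — age-related loss of skeletal muscle mass and function — is
common in elderly patients with acute ischaemic stroke and is associated
with worse functional outcomes. Temporal muscle thickness (TMT), measured
on routine brain MRI in millimetres and averaged over the left and right
sides, is a practical imaging surrogate: unlike grip-strength or
bioimpedance testing it requires no patient cooperation. The package
implements the full analysis chain for asking *how* low TMT relates to
poor outcome: through dysphagia, through early neurological deterioration
(END), through period-specific failure of recovery, and whether presenting
symptoms or infarct locations modify the effect.

The pipeline has five stages, each usable on its own:

1. **Outcome derivation** (`derive_outcomes()`) — fixed clinical rules
   applied to raw registry records.
2. **Effect estimation** (`odds_ratio_2x2()`, `adjusted_effect()`,
   `interaction_scan()`) — crude 2×2 statistics and multivariable
   logistic models, maximum likelihood (ML) or Firth-penalized.
3. **Mediation** (`mediate()`) — counterfactual decomposition of the
   exposure effect through parallel binary mediators.
4. **Brain mapping** (`merge_atlases()`, `roi_burden()`,
   `map_interactions()`, `pool_symmetric()`) — ROI-wise
   lesion-by-exposure effect modification.
5. **Synthetic cohorts** (`simulate_cohort()`, `simulate_lesions()`,
   `simulate_study()`) — a generator with planted effects so every stage
   has a testable ground truth.

## Derivation rules

All rules are deterministic and emitted with their bookkeeping (cutoffs,
exclusion tallies) so a run is auditable from its manifest.

* **Exposure.** Low TMT is TMT below the cohort 25th percentile, computed
  by linear interpolation between order statistics (`quantile()` type 7).
  Ties at the cutoff go to the *high* group, i.e. the low group is a
  strict inequality. The same rule serves TMT/height² (mm/m²), the
  height-normalized sensitivity exposure. The convention identifier is
  always carried in the `cutoff_spec` so a change of convention is
  visible, because different quantile conventions move the cutoff by up
  to one inter-subject gap.
* **Dysphagia.** Functional Oral Intake Scale (FOIS) 1–6; FOIS 7
  (total oral diet without restriction) is non-dysphagic.
* **END.** Any of four criteria within 21 days of onset: total NIHSS
  increment ≥ 2; consciousness subscore (items 1a–1c) increment ≥ 1;
  motor subscore (items 5a–6b) increment ≥ 1; or a clinically recorded
  new neurological deficit. END₄ is the stricter total increment ≥ 4.
  Increments are measured against the *running minimum* of all preceding
  exams, not only the admission exam. The reference exam is a genuinely
  open design point: "any worsening within 3 weeks" describes worsening
  events, and an admission-only comparison would miss deterioration
  after early improvement; both conventions are implemented
  (`reference = "running_min"` or `"admission"`) with running-minimum
  the default. The running-minimum rule is equivalent to enumerating
  all ordered exam pairs, which is how the test suite checks it.
* **Recovery.** Three disjoint windows with their own eligibility:
  in-hospital (NIHSS improvement ≥ 4 points *or* ≥ 40% from admission to
  discharge; admission NIHSS 0 ineligible), post-discharge (3-month mRS
  strictly below discharge mRS; discharge mRS 0 or 6 ineligible), and
  chronic (1-year mRS strictly below 3-month mRS; 3-month mRS 0 or 6 or
  missing 1-year follow-up ineligible). Ineligible is distinct from "no
  recovery" throughout (`NA` vs `FALSE`). The ≥ 40% comparison is done
  as an exact integer inequality (`10 * delta >= 4 * admission`), so no
  floating-point representation of 0.4 is involved.
* **Missing infarct volume** is replaced by the cohort median, with the
  imputation count reported.

## Logistic estimation

`fit_logistic()` implements IRLS on the score equations, declaring
convergence when the largest absolute score component falls below 1e-8
(at most 100 iterations, with step-halving on the objective). The Firth
variant solves the Jeffreys-prior–modified score
$U^*_j(\beta) = \sum_i \{y_i - \pi_i + h_i(\tfrac12 - \pi_i)\} x_{ij}$,
where $h_i$ are the hat-diagonals of the weighted design; its objective
is the penalized log-likelihood $\ell(\beta) + \tfrac12 \log |I(\beta)|$.
Firth estimates stay finite under complete or quasi-complete separation
and carry less small-sample bias, which matters in rare-event subgroup
and ROI models.

Separation under ML is flagged when any non-constant column's
coefficient passes 15 in absolute value or the information matrix
becomes numerically singular; the intercept is exempt because with
covariates on raw clinical scales (cholesterol in mg/dL, haemoglobin in
g/dL) its true value is legitimately large. Model selection is
automatic unless forced: Firth is used when events or non-events are
fewer than 8 in any declared stratum, or when ML flags separation. In
registry-scale cohorts the rare "other determined" stroke-subtype level
regularly produces a zero-event indicator, so the Firth fallback is the
common path for adjusted models — as penalized models were for the rare
subgroup analyses this design mirrors.

Inference is Wald throughout (estimates ± 1.96 SE on the log-odds scale),
matching the OR/CI reporting style; likelihood-ratio inference was
deliberately not mixed in. The predefined covariate set
(`covariate_set()`) is fixed in order: age, sex, admission NIHSS, BMI,
pre-stroke mRS, previous stroke, hypertension, diabetes,
hyperlipidaemia, atrial fibrillation, coronary artery disease, smoking,
stroke subtype (reference level: large-artery atherosclerosis, the most
frequent), revascularization therapy, haemoglobin, total cholesterol,
and median-imputed infarct volume. Continuous-TMT effects are reported
per 1 mm *decrease* by negating the fitted coefficient.

## Mediation

`mediate()` uses the counterfactual (natural-effects) formulation with
parallel, non-interacting mediators given exposure and covariates: one
logistic model per mediator (mediator ~ exposure + covariates) and one
outcome model (outcome ~ exposure + all mediators + covariates).
Counterfactual means $E[Y(x, M(x'))]$ are computed by Monte-Carlo
integration over mediator draws (common random numbers across exposure
settings), and effects are decomposed on the **risk-difference scale**:
total = $E[Y(1,M(1))] - E[Y(0,M(0))]$, natural direct =
$E[Y(1,M(0))] - E[Y(0,M(0))]$, natural indirect = the remainder, so
total = direct + combined indirect holds exactly by construction.
Per-mediator indirect effects shift one mediator's distribution at a
time and sum to the combined effect only approximately (the outcome
model is nonlinear); the Monte-Carlo standard errors needed to judge
that gap are returned. The risk-difference scale was chosen because a
"proportion mediated" is ill-defined on the odds-ratio scale when the
outcome is common (33–60% event rates here). The proportion mediated is
reported only when total and indirect effects share a sign.

Uncertainty comes from a percentile bootstrap over subjects with full
model refits per replicate (≥ 200 replicates for reported intervals);
everything is deterministic given the seed. Candidate mediators pass an
entry screen first: adjusted exposure→mediator and mediator→outcome
associations must both be significant at p < 0.05 (Wald). Post-discharge
recovery is allowed as a mediator of the 3-month outcome even though the
two windows overlap temporally; this mirrors the source design and is a
known interpretive caveat, not a software constraint.

## Brain mapping

Atlases are merged by priority — brainstem labels beat AAL-like labels
beat JHU-like white-matter labels on contested voxels — and per-subject
lesion burden in each merged ROI is the lesioned volume as a percentage
of total brain volume, the same scale as the total-infarct covariate.
(% of ROI volume would weight small tracts differently; % of brain keeps
coefficients comparable across ROIs and was fixed as the design choice.)
Each ROI gets one logistic model: outcome ~ ROI burden + low TMT +
burden×low-TMT product + the predefined covariates *minus* total infarct
volume (collinear with the burden regressor). Significance is the raw
Wald p-for-interaction < 0.05 with **no multiplicity correction** — a
deliberate replication of the source convention and a documented
limitation, not an oversight; `alpha` is exposed for users who want a
different flag threshold, and p-values are returned so any correction
can be applied downstream.

ROIs with no lesioned subject are skipped; ROIs where all lesioned
subjects fall in one exposure group are skipped with a reason (the
product term is aliased); ROIs with fewer than 5 lesioned subjects are
fitted with Firth and flagged `low_support`. The pre-planned symmetric
pooling sums left and right homologous burdens per subject (midline ROIs
pass through), which roughly doubles the lesioned-subject count per ROI
— a √2 gain in the interaction z — since small lesions essentially never
straddle both hemispheres.

A calibration caveat established by simulation in this package: with
lesion sizes matched to the registry's volume distribution (median
0.07% of brain), most ROI overlaps are a few voxels, the product term
carries little information, and the Wald p-for-interaction is
*conservative* — the global-null flag rate comes out near 0.01–0.02
rather than 0.05. The mapping therefore errs toward missing weak
effects, not toward false discoveries; exact nominal calibration is not
attainable in this lesion-size regime with either Wald or
likelihood-ratio p-values.

## The synthetic cohort generator

`simulate_cohort()` draws covariates from the registry's baseline
marginals: age ~ N(75.3, 6.1) truncated to ≥ 65, 50.5% male, BMI ~
N(23.9, 3.3) with weight derived from BMI and height (so the BMI
identity holds exactly), sex-specific height and haemoglobin chosen to
reproduce the overall means and SDs, comorbidity prevalences as
published, and smoking given sex (70% male / 16.5% female smokers)
so the crude smoking–TMT association arises through sex rather than
being planted. TMT is a linear model in sex and age — 5.99 + 1.40·male
− 0.06·(age − 75.3) + N(0, 1.95), truncated at 1 mm — which reproduces
the male/female imbalance of the low-TMT group (≈ 25% male) without
claiming the unobserved joint distribution. Admission NIHSS is negative
binomial with its mean tied mildly to TMT (lower TMT, higher severity),
giving a median of 4 and roughly 9% zeros; infarct volume is lognormal
with median ≈ 0.07% of brain and a heavy tail.

Mediators and outcomes are drawn from logistic models whose coefficients
are the `effect_sizes` configuration; the defaults are the published
adjusted odds ratios (dysphagia 1.89, END 2.75, in-hospital recovery
0.67, post-discharge recovery 0.56, chronic recovery 1.13), plus fixed
mediator-to-outcome and direct-effect choices (direct 1.8; dysphagia
1.9, END 2.5, post-discharge recovery 0.35 on the 3-month poor-outcome
flag) that produce a partially mediated exposure effect. Zeroing the
exposure entries yields a valid global null.

Serial NIHSS exams are generated at days 0, 2, 5 and 10 as a *nested*
non-increasing decline (items only ever lose points between exams), with
the discharge total set by the planted in-hospital recovery intent. END
events are injected on top: the qualifying increment (total ≥ 2/4,
motor + 1, consciousness + 1, or a new-deficit flag) is added at day 2
or 5 relative to the *realized running minimum*, persisting to discharge
in half the cases. Because non-END trajectories are monotone, the
derived END flag equals the planted one exactly — the derivation rules,
not trajectory realism, are the test target. Symptomatic haemorrhagic
transformation cause labels are always paired with a ≥ 4-point rise so
the cause-validation rule has a clean positive class.

mRS trajectories are built to respect the ordinal constraints (death is
absorbing; recovery means a strictly lower score). Where the planted
post-discharge recovery intent and the drawn 3-month poor-outcome flag
are jointly impossible (e.g. "recovered" from discharge mRS ≤ 3 while
staying ≥ 3), the outcome draw wins and the recovery intent flips;
agreement between the drawn and derived poor-outcome flag is ≈ 98%, and
the small attenuation lands on the recovery effects. One-year mRS is
lost to follow-up at the configured rate (default 20/580).

One global seed is expanded into independent substreams (covariates,
outcomes, lesions, mapping outcomes, mediation) through two rounds of
Lehmer mixing, so changing one stage's configuration never perturbs
another stage's draws, and a fixed seed reproduces everything
bit-identically.

**Lesions and atlases.** `simulate_lesions()` grows one contiguous blob
per subject on a 20×20×20 toy grid of 1 mm³ voxels (the whole grid is
"brain"), seeded uniformly, with lognormal sizes matched to the infarct
volume distribution (median ≈ 6 voxels ≙ 0.07% of brain, capped at 600).
The toy atlases provide left/right homologous labels (cortex, pallidum,
cerebellum; corticospinal and fronto-pontine tract columns) and a
midline brainstem set (midbrain/pons/medulla plus left/right middle
cerebellar peduncles) with deliberate overlaps so priority merging is
exercised. Nothing about the toy template is neuroanatomically
realistic — it shares only the *statistical* structure (contiguity,
laterality, size distribution, atlas overlap) that the mapping machinery
depends on. Passing tests therefore validate the derivation, estimation
and mapping logic, not the behaviour of real DWI masks, registration
quality, or anatomical lesion topography.

**Planted mapping scenarios.** For detection-power studies the
per-%-burden interaction coefficients were chosen a priori from pilot
Wald standard errors to target ≈ 0.9 power at n = 2000: a single-ROI
scenario (left cortex, β = 7; its frequent, larger lesions make it the
best-identified ROI) and a bilateral scenario (both cerebellar labels,
β = 9) in which each side alone is underpowered (~0.5) but the pooled
column is not (~0.85–0.9) — the designed demonstration of the symmetric
pooling rationale. With these tiny lesions a "detectable" effect is
necessarily large per unit burden (β·burden ≈ 0.5–1 log-odds for a
typical overlap); that is a property of the lesion-size regime, not of
the estimator.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: parameter recovery at
n = 5000 over 100 replicates (plus one n = 50 000 refit), mediation at
n = 1200–2000 with 200 bootstrap replicates and 100–400 Monte-Carlo
draws, mapping power at n = 2000 over 200 replicates, the global null
at n = 600 (registry scale) over 200 cohorts, and rule-derivation
oracles over 1000 random trajectories. These sizes were chosen so each
distributional claim has its Monte-Carlo error well inside the asserted
margin. Other numerical choices: IRLS tolerance 1e-8 on the score with
step-halving; weights floored at 1e-12; Haldane–Anscombe 0.5 correction
(flagged) for zero cells in 2×2 tables; Fisher's exact test replaces the
chi-square when any expected cell is below 5; Shapiro–Wilk at p > 0.05
in both groups (subsampled at 5000) decides t-test vs Mann–Whitney.

## Known limitations

* The generator plants *marginal* structure and a specific causal
  ordering; inter-covariate correlations beyond those described (TMT
  with sex/age/NIHSS, smoking with sex) are not modelled, and are a
  documented choice rather than an inference from data.
* The mediation estimator assumes parallel, non-interacting mediators;
  sequential or interacting mediator structures are out of scope.
* ROI significance is uncorrected by design; with ~15 ROIs per outcome
  the family-wise error is appreciable even though the per-test rate is
  conservative here.
* Wald p-for-interaction is conservative for sparse, skewed burden
  regressors (see above); power statements for small ROIs should be read
  accordingly.
* Real-data ingestion expects records already in the exchange schema
  (cohort CSV + long NIHSS CSV + masks/atlases in one template space);
  image segmentation, registration and TMT caliper measurement are out
  of scope.
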