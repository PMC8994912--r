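---
title: "Episode-based costing of type 2 diabetes complications: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episode-based costing of type 2 diabetes complications: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospital registers record type 2 diabetes (T2D) complications as streams of
dated diagnosis codes and admission-level billing records. To estimate what
a complication *costs*, those streams have to be turned into an analysable
unit — the complication **episode** — and the billing records have to be
attributed to time windows around it. `epicost` implements that whole chain:
episode construction, cost windowing and deflation, gamma regression of
one-year costs with cluster-robust inference, average marginal effects, and
Cholesky-based predictive simulation, together with a synthetic registry
generator so every stage can be validated end to end without access to
patient-level data (which, for the real Finnish registers this design
mirrors, are not publicly available).

## Episode construction

Diagnosis codes map to six complication classes (cerebrovascular,
cardiovascular, nephropathy, foot disorder, eye, neurological) by
configurable prefix lists; matching is case-insensitive and ignores the
ICD-10 dot, because registers mix dialects. Within each (patient, class)
stream the first diagnosis opens an episode at its **index date** and every
repeat diagnosis of the same class within 365 days of the index belongs to
the same episode (`from_index` rule). The register convention could also be
read as "a new event after at least a year of silence", so a `rolling_gap`
variant (split when the gap since the *previous event* reaches 365 days) is
implemented behind a flag; the two rules differ on histories like days
{0, 300, 600} and both are tested against independent brute-force oracles.
We use whole 365-day years and 730-day comorbidity windows throughout — no
leap-day handling, since a one-day boundary shift is far below every other
source of imprecision in register data.

Episodes are **prediabetic** when the index precedes the T2D diagnosis,
otherwise **incident** when no earlier episode falls within a 15-year
look-back, else **recurrent**. The default history scope counts episodes of
*any* class (an eye episode after a cardiovascular one is recurrent),
matching the framing of "patients with no history of T2D-related
complications"; a same-class scope is available by flag. Prediabetic
episodes count toward the history. Comorbidities follow the Charlson
classes, modified: HIV/AIDS, hemiplegia/paraplegia and uncomplicated
diabetes dropped, the two liver and two malignancy classes merged, diabetes
with chronic complications retained; a flag is set when a matching code
occurs in the half-open window `[index − 730, index)`. The main analysis
keeps incident and recurrent episodes with index dates in 2012–2016
(inclusive on both ends) for patients in the catchment area.

## Cost attribution

Costs are time-stamped to their accounting/discharge date, deflated to
2019 euros by a year-indexed price deflator, and summed into three
half-open windows: the pre-year `[index − 365, index)`, year 1
`[index, index + 365)` (the primary outcome) and year 2
`[index + 365, index + 730)`. The index day itself belongs to year 1; the
convention is ours, the mechanics of accounting dates decide borderline
admissions. A record may legitimately contribute to windows of two
*different* classes' overlapping episodes — classes are analysed
independently and no cross-class deduplication is attempted. The recurrent
models use an indicator for an exceptionally expensive previous same-class
episode (strictly above 50 000 €, a static cut chosen to sit near the 90th
percentile of year-1 costs); `threshold_percentile_check()` reports where
the cut actually falls in the data, as a diagnostic only.

## The cost model

One-year costs are positive and right-skewed, so each (class × episode
type) stratum gets a gamma GLM with log link, `E[y|x] = exp(x'β)`.
Covariates: sex, age at index (centred at 75, per decade), T2D duration
(per 5 years), death within one year of the index, and the comorbidity
flags; recurrent models add the number of earlier same-class episodes, the
high-previous-cost indicator and the diabetes-with-chronic-complications
flag. Exponentiated coefficients are cost ratios against the reference
profile (75-year-old man, newly diagnosed, no comorbidities, alive at one
year), whose predicted cost is the exponentiated intercept in euros.

Fitting is IRLS (`stats::glm`) with tolerance 1e-8 and at most 100
iterations; zero-cost episodes are excluded with a logged count (gamma
support is positive; episodes are anchored on an admission so they are
essentially always cost-positive), and zero-variance covariates are dropped
with a warning naming them — the analogue of an inestimable comorbidity in
a stratum where it never occurs. The shape parameter is estimated from the
deviance (`n/deviance`); under the log link it does not affect the
coefficients. Inference uses the cluster-robust sandwich covariance
(`sandwich::vcovCL`, patients as clusters, G/(G−1) small-sample factor),
uniformly for incident and recurrent models: the motivation is repeated
episodes of one patient, and for incident models — where clusters are
essentially singletons — the estimator reduces to the ordinary
heteroskedasticity-robust one, so uniformity costs nothing. P-values are
normal-approximation on the log scale, starred at 0.05/0.01, with no
multiple-testing correction. McFadden's pseudo-R² is `1 − ℓ/ℓ₀` from the
fitted and intercept-only log-likelihoods. Average marginal effects use the
log-link identities: `β_j ×` mean prediction for continuous covariates, the
mean counterfactual difference for binary ones. The twelve models fit
independently; one failure never aborts the rest.

## Predictive simulation

Coefficient uncertainty propagates by drawing `β + Lz` with `LL'` the
lower-triangular Cholesky factor of the chosen covariance (sandwich by
default; model-based optionally) and summarising `exp(x'β_draw)` over
10 000 draws. A numerically semi-definite covariance receives a 1e-10
diagonal jitter (logged); an all-zero covariance gives draws degenerate at
the point prediction, which ties the simulator to `predict_mean()` exactly.
Patient-level gamma outcome noise is opt-in, off by default: the printed
tables describe mean costs, and whether the original interactive tool added
outcome noise is not stated, so the conservative default reports
uncertainty in the *mean*. `refit_subset_model()` reproduces the
interactive-tool primitive of fitting on a user-chosen covariate subset; an
empty subset yields the closed-form intercept-only fit.

## The synthetic registry

The generator emulates the structure the analysis assumes, with defaults
fixed at the study conditions the package targets:

* timeline 1996–2017, inclusion era 2012–2016; ~2 % of patients without a
  T2D diagnosis; 45 % female; age ~N(66, 13²) at the start of 2012; T2D
  onset uniform over 1996–2016, so prediabetic episodes and short-duration
  cases genuinely occur;
* per-class episode hazards 0.0216/0.0703/0.0097/0.0220/0.0300/0.0035 per
  person-year (cerebrovascular/cardiovascular/nephropathy/foot/eye/
  neurological) — the published per-class episode counts divided by the
  published person-years;
* true log-scale coefficients equal to the log of the published
  exponentiated coefficient tables (an inestimable printed cell is treated
  as ratio 1.0), so simulated effect sizes are exactly the reported ones;
* gamma shape 2 for one-year episode costs (CV ≈ 0.71, skewness ≈ 1.41): no
  distributional parameter beyond "positive skewness" is reported for the
  real data, so this is a modelling choice, made once;
* death within one year of an episode with probability 0.10, truncating all
  later events and costs; comorbidity codes planted per episode with
  prevalences between 0.02 and 0.12; a 2 %/year price index so deflation is
  genuinely exercised; low-intensity background costs (0.5 records per
  person-year, mean 200 €).

Renewal gaps between same-class episodes strictly exceed the 365-day window
so the true episode structure is unambiguous; an `adversarial` mode draws
gaps straddling the boundary to stress the builder. Truth covariates —
including comorbidity flags — are recomputed from the *planted* events by a
deliberately naive scan, and the drawn costs use exactly those covariates,
so a correct pipeline recovers the generating coefficients without
systematic bias. One caveat is inherent to the design: when several classes
are active simultaneously, overlapping one-year windows of different
classes share cost records (as in the real analysis), so parameter-recovery
checks run on single-class registries, where year-1 totals equal the drawn
costs exactly. What the generator does *not* emulate: real ICD-10/NCSP code
lists, DRG billing structure, seasonal admission patterns, cost dependence
between overlapping complications, and informative censoring beyond the
per-episode death draw — so passing tests validate the *machinery*, not the
clinical realism of any particular coefficient.

## Validation surface and problem sizes

The worked examples printed with the original coefficient tables
(8214.077 € and 8172.655 € for the female reference profile under the
incident and recurrent cerebrovascular models, 15.7 episodes per 100
person-years, the six class counts summing to 16 148, the per-group
percentages of men) are recomputed by the package from the shipped printed
tables and asserted to printed precision. Property suites check: both
episode rules against brute-force oracles on 1 000 random histories;
half-open window boundaries on adversarial fixtures; the gamma log-link
closed forms (intercept MLE = sample mean to 10 significant digits, the AME
identity to 1e-8 relative); singleton-cluster sandwich equal to a
hand-rolled HC estimator; and parameter recovery on a single-class registry
of 7 500 patients (≈2 000 incident and ≈6 800 recurrent episodes, every
coefficient within 3 sandwich SEs of truth) with 95 % interval coverage in
[92 %, 98 %] over 200 replicates of n = 2 000 — sizes chosen to make
Monte-Carlo noise small relative to the tested tolerances while keeping the
suite fast enough to run routinely.

## Known limitations

* The register codes shipped are transparent synthetic mnemonics; real code
  lists drop in via the YAML config without code changes.
* Person-years use one fixed convention (entry at the later of window start
  and T2D diagnosis, exit at death or window end, 365.25-day years); the
  original aggregation rule is not documented and other conventions shift
  the denominator by fractions of a percent.
* Zero-cost episodes are excluded rather than modelled (no two-part/hurdle
  layer); with admission-anchored episodes the excluded count is zero or
  negligible.
* The deviance-based shape estimator is mildly biased for the gamma family;
  it is reported for simulation and diagnostics, and never influences
  coefficients or sandwich inference.
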