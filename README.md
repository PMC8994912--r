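# epicost

Episode-based hospital cost analysis for type 2 diabetes (T2D)
complications: an R package for health economists and register
epidemiologists who need to turn longitudinal hospital diagnosis and
billing records into per-complication cost estimates, and to simulate
predicted cost distributions for patient profiles.

## What it does

Starting from three flat tables — patients, dated diagnosis events, and
admission-level cost records — the package:

1. maps diagnosis codes to six complication classes (cerebrovascular,
   cardiovascular, nephropathy, foot disorder, eye, neurological) and to a
   modified set of Charlson comorbidity classes, via configurable prefix
   lists (`load_code_maps`, `classify_code`);
2. groups each (patient, class) diagnosis stream into **episodes**: the
   first diagnosis is the index event and repeat diagnoses within 365 days
   belong to the same episode; episodes are classified prediabetic /
   incident / recurrent with a 15-year look-back
   (`build_all_episodes`, `classify_episodes`);
3. deflates costs to 2019 euros and sums them into half-open windows around
   the index — the pre-year, year 1 (the primary outcome) and year 2
   (`window_costs`, `deflate`);
4. fits one gamma regression with log link per complication class and
   episode type,

   E[y | x] = exp(x'β),

   where y is the one-year cost and x contains sex, age (centred at 75,
   per decade), T2D duration (per 5 years), death within one year,
   comorbidity flags, and — for recurrent episodes — the number of earlier
   same-class episodes and an indicator for an exceptionally expensive
   (> 50 000 €) previous episode. Standard errors come from the
   cluster-robust sandwich estimator with patients as clusters;
   exponentiated coefficients, significance stars, McFadden pseudo-R² and
   average marginal effects in euros are reported (`fit_gamma_glm`,
   `coefficient_table`, `average_marginal_effects`);
5. simulates predicted one-year cost distributions for covariate profiles
   by drawing coefficient vectors β + Lz through the Cholesky factor
   LL' = Σ of the coefficient covariance (`simulate_cost_distribution`).

Because the patient-level registry data this design targets cannot be
shared, the package ships a **synthetic registry generator**
(`simulate_registry`) with known ground truth — planned episodes, planted
comorbidities, gamma-distributed one-year costs with log-linear covariate
effects — so the entire pipeline is testable end to end, including exact
episode recovery and coefficient recovery within sampling error.

## Worked example

Point predictions from a published-style coefficient table (intercept in
euros, other coefficients exponentiated):

```r
library(epicost)
inc <- published_model("cerebrovascular", "incident")
predict_mean(inc)                                   # men at reference
#> [1] 9663.62
predict_mean(inc, c(woman = 1))                     # women at reference
#> [1] 8214.077
predict_mean(inc, c(woman = 1, age_c75_per10 = 1))  # 85-year-old woman
#> [1] 6653.402
```

The reference profile is a 75-year-old man with newly diagnosed T2D, no
recorded comorbidity, alive one year after the event; each activated
covariate multiplies the intercept euros by its exponentiated coefficient
(0.85 × 9663.62 = 8214.077 for female sex, then × 0.81 per decade of age).

A full synthetic run, from generator to fitted models to a predictive
distribution:

```r
cfg <- sim_config(n_patients = 1000, rng_seed = 42)
res <- run_pipeline(cfg)
nrow(res$included)        # 432 episodes with index dates in 2012-2016
res$incidence_rate        # 14.1 per 100 person-years

fit <- res$models[["cardiovascular:recurrent"]]
fit
#> Gamma log-link cost model: n = 158, clusters = 145, shape = 2.062
#>   intercept 8705.82 EUR, pseudo-R2 0.019

simulate_cost_distribution(fit, c(woman = 1), n_draws = 10000, seed = 42)
#> Simulated one-year cost distribution (10000 draws, sandwich covariance)
#>   mean 7507.14 EUR, sd 1441.46
#>     2.5%      25%      50%      75%    97.5%
#>  5051.98  6492.62  7378.06  8383.33 10666.48
```

The simulated spread reflects coefficient uncertainty only (the default);
patient-level gamma outcome noise is available with
`include_outcome_noise = TRUE`.

## Analysis workflow

The `analysis/` scripts run the study pipeline as numbered steps, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate_registry.R   # synthetic registry + truth sidecar
Rscript analysis/02_build_episodes.R      # episodes, classification, incidence
Rscript analysis/03_attribute_costs.R     # deflation, windows, cost indicator
Rscript analysis/04_fit_cost_models.R     # 12 gamma models, AMEs, descriptives
Rscript analysis/05_predict_profiles.R    # Cholesky predictive simulation
```

See `vignettes/cost-of-complications.Rmd` for the modelling assumptions,
parameter defaults and design decisions.

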