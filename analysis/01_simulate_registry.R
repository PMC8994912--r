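#!/usr/bin/env Rscript
# Step 1 — simulate the synthetic hospital registry.
#
# Generates a cohort of people with type 2 diabetes, their complication
# diagnosis events over a 1996-2017 timeline, and admission-level cost
# records whose one-year episode sums are gamma-distributed with log-linear
# covariate effects (true coefficients = log of the printed model tables).
# Writes the registry CSVs plus the ground-truth sidecar.

library(epicost)

cfg <- sim_config(n_patients = 2000, rng_seed = 20260929)
reg <- simulate_registry(cfg)
write_registry(reg, "results/registry")

cat(sprintf("cohort: %d patients (%.1f%% female, %.1f%% with T2D)\n",
            nrow(reg$patients), 100 * mean(reg$patients$sex == "female"),
            100 * mean(!is.na(reg$patients$t2d_diagnosis_date))))
cat(sprintf("events: %d diagnoses, %d cost records\n",
            nrow(reg$diagnoses), nrow(reg$costs)))
cat(sprintf("planned episodes: %d (%s)\n", nrow(reg$truth),
            paste(names(table(reg$truth$episode_type)),
                  table(reg$truth$episode_type), collapse = ", ")))
cat("registry written to results/registry/\n")
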