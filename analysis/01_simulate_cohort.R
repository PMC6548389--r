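#!/usr/bin/env Rscript
# Step 1: simulate the longitudinal cohort the downstream analyses consume.
#
# Emulated design: 33 early-preeclampsia cases / 90 normal pregnancies,
# prenatal visits every ~4 weeks from 8-12 weeks of gestation with 2-6
# profiled plasma samples per patient, case diagnosis between 24.6 and 33.4
# weeks, a 200-protein panel with 4 planted markers (log2 MoM shift 1.0,
# staggered onsets). A marker-free cohort is generated alongside for
# calibration checks. Writes the cohort files, covariates and ground truth
# under results/.

library(pepanel)

seed <- 20260922L
dir.create("results", showWarnings = FALSE)

gen <- generate_cohort(synth_config(), seed = seed)
write_cohort(gen$cohort, "results/cohort_synthetic.csv")
write_covariates(gen$cohort$covariates, "results/covariates_synthetic.csv")
jsonlite::write_json(
  list(markers = gen$truth$markers, tau = gen$truth$tau,
       sigma = gen$truth$sigma, seed = seed),
  "results/ground_truth.json", auto_unbox = TRUE, digits = NA)

gen0 <- generate_cohort(synth_config(markers = NULL), seed = seed)
write_cohort(gen0$cohort, "results/cohort_null.csv")
write_covariates(gen0$cohort$covariates, "results/covariates_null.csv")

s <- cohort_summary(gen$cohort)
message(sprintf(
  "cohort: %d proteins; %d cases (%d MVM, %d severe) / %d controls",
  s$n_proteins, s$n_cases, s$n_mvm, s$n_severe, s$n_controls))
message(sprintf(
  "median pre-diagnosis samples: %.0f (cases) / %.0f (controls); diagnosis GA %.1f-%.1f weeks",
  s$median_prediag_samples_cases, s$median_prediag_samples_controls,
  s$diagnosis_ga_range[1], s$diagnosis_ga_range[2]))
message("interval occupancy (pre-diagnosis samples): ",
        paste(names(s$interval_occupancy), s$interval_occupancy,
              sep = "=", collapse = ", "))
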