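#!/usr/bin/env Rscript
# Step 2: gestational-age normalization. Thresholds outliers at twice the
# 98th percentile, fits per-protein cubic-spline mixed-effects reference
# curves on the control group, and expresses every sample as a multiple of
# the gestational-age-specific control mean (MoM). Writes the frozen
# reference curves (JSON) and the MoM cohort.

library(pepanel)

cohort <- read_cohort("results/cohort_synthetic.csv",
                      covariates_path = "results/covariates_synthetic.csv")
curves <- fit_reference_curves(cohort)
mom <- to_mom(cohort, curves)

write_reference(curves, "results/reference_curves.json")
write_cohort(mom, "results/cohort_mom.csv")

is_ctrl <- mom$meta$EarlyPE != 1
lm2 <- log2(mom$abundance[is_ctrl, ])
message(sprintf(
  "fitted %d reference curves; control log2 MoM mean %.4f (sd %.3f)",
  length(curves$panel), mean(lm2), sd(lm2)))
message(sprintf(
  "median variance components across proteins: tau = %.3f, sigma = %.3f log2 units",
  median(sqrt(curves$tau2)), median(sqrt(curves$sigma2))))
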