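#!/usr/bin/env Rscript
# Step 3: parsimonious marker panels per gestational-age interval. One
# pre-diagnosis sample per patient per interval, 10% MoM-change filter,
# single-marker leave-one-patient-out pAUC ranking, nested forward
# acceptance under the +0.01 pAUC rule (panel size <= 5), final linear
# discriminant refit on the full interval view.

library(pepanel)

mom <- read_cohort("results/cohort_mom.csv")
mom$scale <- "mom"
labeled <- define_contrast(mom, "all_early_pe")

intervals <- c("8-16", "16.1-22", "22.1-28", "28.1-32")
rows <- lapply(intervals, function(iv) {
  v <- select_interval_view(labeled, iv)
  p <- build_panel(v)
  message(sprintf("%-8s %2d cases /%3d controls -> %s", iv,
                  sum(v$patients$label == "case"),
                  sum(v$patients$label == "control"),
                  if (length(p$proteins)) paste(p$proteins, collapse = " + ")
                  else "(empty panel)"))
  data.frame(interval = iv,
             n_cases = sum(v$patients$label == "case"),
             n_controls = sum(v$patients$label == "control"),
             panel = paste(p$proteins, collapse = ";"),
             panel_size = length(p$proteins),
             loocv_pauc = if (nrow(p$trace)) p$trace$pauc[nrow(p$trace)]
                          else NA_real_,
             status = p$status)
})
out <- do.call(rbind, rows)
write.csv(out, "results/panels_by_interval.csv", row.names = FALSE)
message("wrote results/panels_by_interval.csv")
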