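#!/usr/bin/env Rscript
# Step 6: over-representation analysis of differentially abundant proteins
# against the assay panel background (one-sided hypergeometric test, >= 3
# hits and q < 0.1 for significance). Term annotation here is a synthetic
# GMT built around the simulation's ground truth: one biological-process
# term containing the planted markers plus bystanders, and size-matched
# unrelated terms; with real data, supply a curated GMT instead.

library(pepanel)

mom <- read_cohort("results/cohort_mom.csv")
panel <- mom$panel
truth <- jsonlite::read_json("results/ground_truth.json",
                             simplifyVector = TRUE)
markers <- truth$markers$protein
nulls <- setdiff(panel, markers)

gmt_path <- "results/terms_synthetic.gmt"
terms <- list(planted_process = c(markers, nulls[1:6]),
              membrane_organization = nulls[7:26],
              ion_transport = nulls[27:41],
              rna_processing = nulls[42:51])
writeLines(vapply(names(terms), function(tm)
  paste(c(tm, "synthetic annotation", terms[[tm]]), collapse = "\t"),
  character(1)), gmt_path)

hits_by_iv <- read.csv("results/diff_abundance_counts.csv")
rows <- lapply(hits_by_iv$interval[hits_by_iv$n_significant_q10 > 0],
               function(iv) {
  tab <- read.csv(sprintf("results/diff_abundance_%s.csv",
                          gsub("\\.", "_", iv)))
  hits <- tab$protein[bh_qvalues(tab$p) < 0.1]
  enr <- fisher_ora(hits, read_gmt(gmt_path, background = panel), panel)
  enr$interval <- iv
  sig <- enr[enr$significant, ]
  message(sprintf("%-8s %d hit(s); %d enriched term(s)%s", iv, length(hits),
                  nrow(sig),
                  if (nrow(sig)) paste0(": ", paste(
                    sprintf("%s (N=%d, OR=%.1f, q=%.3f)", sig$term,
                            sig$n_hits, sig$odds_ratio, sig$q),
                    collapse = "; ")) else ""))
  enr
})
out <- do.call(rbind, rows)
write.csv(out, "results/enrichment.csv", row.names = FALSE)
message("wrote results/enrichment.csv")
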