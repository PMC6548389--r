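# Parsimonious marker-panel construction: 10% MoM-change filter, per-protein
# leave-one-patient-out pAUC ranking, and forward acceptance of nested
# top-k sets (k <= 5) under a +0.01 pAUC gain rule.

#' Filter proteins by fold change of mean MoM
#'
#' A protein is retained iff the arithmetic mean of its linear MoM values in
#' cases differs from the control mean by at least `delta` in relative terms:
#' `|mean(MoM_cases) / mean(MoM_controls) - 1| >= delta` (boundary
#' inclusive).
#'
#' @param mom linear-scale MoM matrix (patients by proteins).
#' @param labels `"case"`/`"control"` vector.
#' @param delta minimum relative change (default 0.10).
#' @return Character vector of retained protein identifiers (in panel order).
#' @export
fold_change_filter <- function(mom, labels, delta = 0.10) {
  is_case <- as_case_indicator(labels)
  if (!any(is_case) || all(is_case))
    stop("both groups must be non-empty", call. = FALSE)
  m1 <- colMeans(mom[is_case, , drop = FALSE])
  m0 <- colMeans(mom[!is_case, , drop = FALSE])
  # small epsilon keeps the boundary inclusive under floating point
  keep <- abs(m1 / m0 - 1) >= delta - 1e-12
  colnames(mom)[keep & is.finite(m1 / m0)]
}

#' Rank proteins by single-marker leave-one-out pAUC
#'
#' Each protein's out-of-fold linear-discriminant scores (leave one patient
#' out) are summarized by the partial AUC over FPR in `[0, fpr_cap]`.
#' Ties are broken by full AUC, then by protein identifier, so the ranking is
#' fully deterministic.
#'
#' @param x log2 MoM matrix (patients by proteins).
#' @param labels `"case"`/`"control"` vector.
#' @param fpr_cap FPR cap for the partial AUC.
#' @return data.frame `(protein, pauc, auc)` sorted by decreasing pAUC.
#' @export
rank_markers <- function(x, labels, fpr_cap = 0.5) {
  sc <- loocv_scores_univariate(x, labels)
  is_case <- as_case_indicator(labels)
  met <- apply(sc, 2, function(s) {
    m <- roc_metrics(s, is_case, fpr_cap = fpr_cap)
    c(m$pauc, m$auc)
  })
  out <- data.frame(protein = colnames(x), pauc = met[1, ], auc = met[2, ],
                    stringsAsFactors = FALSE)
  out[order(-out$pauc, -out$auc, out$protein), , drop = FALSE]
}

#' Build a parsimonious marker panel
#'
#' Implements the study's selection rule on one interval view: (1) drop
#' proteins failing the `delta` MoM-change filter; (2) compute single-marker
#' leave-one-patient-out pAUC for every survivor and rank them; (3) candidate
#' models are the nested top-1, top-2, ..., top-`k_max` prefix sets of that
#' ranking; (4) the size-(k+1) set is accepted only if its leave-one-out pAUC
#' is at least `pAUC(k) + gain`, stopping at the first rejection; (5) the
#' final linear discriminant is refitted on all patients with the accepted
#' set. Selection involves no randomness: identical views give identical
#' panels.
#'
#' @param view an `interval_view` in linear MoM space (see
#'   [select_interval_view()]); discriminants operate on log2 MoM.
#' @param k_max maximum panel size (default 5).
#' @param gain minimum pAUC improvement to accept an additional protein
#'   (default 0.01, on the unnormalized pAUC scale in `[0, fpr_cap]`).
#' @param delta MoM-change filter threshold (default 0.10).
#' @param fpr_cap FPR cap for the pAUC (default 0.5).
#' @return A `marker_panel`: list with `proteins` (ordered, possibly empty),
#'   `fit` (`lda_fit` on the full view, or `NULL`), `trace` (accepted sizes
#'   and their pAUCs), `ranking`, `status` and the rule parameters.
#' @export
build_panel <- function(view, k_max = 5, gain = 0.01, delta = 0.10,
                        fpr_cap = 0.5) {
  stopifnot(inherits(view, "interval_view"))
  panel_from_matrix(view$mom, view$patients$label, k_max = k_max,
                    gain = gain, delta = delta, fpr_cap = fpr_cap)
}

# core selection on a raw (linear MoM) matrix + labels; used by build_panel
# and by every resampling iteration.
panel_from_matrix <- function(mom, labels, k_max = 5, gain = 0.01,
                              delta = 0.10, fpr_cap = 0.5) {
  kept <- fold_change_filter(mom, labels, delta = delta)
  empty <- list(proteins = character(0), fit = NULL,
                trace = data.frame(size = integer(0), pauc = numeric(0)),
                ranking = NULL, status = "empty: no protein passed the filter",
                k_max = k_max, gain = gain, delta = delta, fpr_cap = fpr_cap)
  class(empty) <- "marker_panel"
  if (length(kept) == 0) return(empty)
  x <- log2(mom[, kept, drop = FALSE])
  ranking <- rank_markers(x, labels, fpr_cap = fpr_cap)
  k_try <- min(k_max, nrow(ranking))
  sizes <- integer(0)
  paucs <- numeric(0)
  status <- "reached k_max"
  for (k in seq_len(k_try)) {
    set_k <- ranking$protein[seq_len(k)]
    pauc_k <- if (k == 1) {
      ranking$pauc[1]
    } else {
      sc <- loocv_scores(x[, set_k, drop = FALSE], labels)
      roc_metrics(sc, labels, fpr_cap = fpr_cap)$pauc
    }
    if (k > 1 && pauc_k < paucs[length(paucs)] + gain) {
      status <- sprintf("stopped at size %d: +%.3f gain rule", k - 1, gain)
      break
    }
    sizes <- c(sizes, k)
    paucs <- c(paucs, pauc_k)
  }
  proteins <- ranking$protein[seq_len(max(sizes))]
  fit <- lda_fit(x[, proteins, drop = FALSE], labels)
  structure(list(proteins = proteins, fit = fit,
                 trace = data.frame(size = sizes, pauc = paucs),
                 ranking = ranking, status = status,
                 k_max = k_max, gain = gain, delta = delta,
                 fpr_cap = fpr_cap),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  if (length(x$proteins) == 0) {
    cat("marker_panel: empty (", x$status, ")\n", sep = "")
  } else {
    cat("marker_panel: ", paste(x$proteins, collapse = " + "),
        "  [LOOCV pAUC ", sprintf("%.3f", x$trace$pauc[nrow(x$trace)]),
        "; ", x$status, "]\n", sep = "")
  }
  invisible(x)
}

#' Score new patients with a fitted panel
#'
#' @param panel a `marker_panel` from [build_panel()].
#' @param mom linear MoM matrix containing at least the panel's proteins.
#' @return Numeric risk scores (0 for every patient when the panel is empty,
#'   i.e. an uninformative constant score).
#' @export
predict_panel <- function(panel, mom) {
  if (length(panel$proteins) == 0) return(rep(0, nrow(mom)))
  lda_score(panel$fit, log2(mom[, panel$proteins, drop = FALSE]))
}
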