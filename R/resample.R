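# Outer resampling around the whole selection pipeline: stratified bootstrap
# (train on the resample, test out-of-bag) and repeated stratified 3-fold
# cross-validation. Panel selection (filter -> rank -> forward acceptance ->
# refit) reruns inside every training set, so the out-of-sample metrics carry
# no selection optimism.

# run the pipeline on a train/test split of a view; returns metrics + panel
run_split <- function(mom, labels, train_idx, test_idx, params) {
  panel <- panel_from_matrix(mom[train_idx, , drop = FALSE],
                             labels[train_idx],
                             k_max = params$k_max, gain = params$gain,
                             delta = params$delta, fpr_cap = params$fpr_cap)
  sc <- predict_panel(panel, mom[test_idx, , drop = FALSE])
  met <- roc_metrics(sc, labels[test_idx], fpr_cap = params$fpr_cap,
                     fpr_target = params$fpr_target)
  list(panel = panel$proteins,
       train = train_idx, test = test_idx,
       auc = met$auc, pauc = met$pauc,
       sensitivity = met$sensitivity_at_fpr,
       specificity = met$achieved_specificity)
}

new_resample_report <- function(scheme, iters, panel, B, seed, params,
                                n_redraws = 0L) {
  metric <- function(f) vapply(iters, `[[`, numeric(1), f)
  agg <- lapply(c(auc = "auc", pauc = "pauc", sensitivity = "sensitivity",
                  specificity = "specificity"), function(f) {
    v <- metric(f)
    list(mean = mean(v), ci = unname(quantile(v, c(0.025, 0.975))))
  })
  counts <- table(factor(unlist(lapply(iters, `[[`, "panel")), levels = panel))
  structure(list(scheme = scheme, B = B, seed = seed, params = params,
                 iterations = iters, aggregates = agg,
                 inclusion = as.numeric(counts) / B * 100,
                 panel = panel, n_redraws = n_redraws),
            class = "resample_report")
}

#' @export
print.resample_report <- function(x, ...) {
  a <- x$aggregates
  cat("resample_report [", x$scheme, ", ", x$B, " iterations, seed ",
      x$seed, "]\n", sep = "")
  for (m in names(a))
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", m, a[[m]]$mean,
                a[[m]]$ci[1], a[[m]]$ci[2]))
  top <- inclusion_frequencies(x)
  if (nrow(top) > 0) {
    cat("  proteins selected in >= 10% of iterations:\n")
    for (i in seq_len(min(8, nrow(top))))
      cat(sprintf("    %s (%.0f%%)\n", top$protein[i], top$percent[i]))
  }
  invisible(x)
}

#' Bootstrap evaluation of the selection pipeline
#'
#' Each of `B` iterations resamples cases and controls separately with
#' replacement to the view's class sizes (stratified bootstrap); patients not
#' drawn form the out-of-bag test set; the full pipeline (MoM-change filter,
#' pAUC ranking, forward panel acceptance, discriminant refit) reruns on the
#' training resample; ROC metrics are computed on the out-of-bag scores.
#' Iterations whose out-of-bag set lacks a class are redrawn so `B` stays
#' fixed (the redraw count is reported). A master seed spawns per-iteration
#' substreams, so iteration `i` is reproducible in isolation and the whole
#' report is a pure function of (view, parameters, seed).
#'
#' @param view an `interval_view` in linear MoM space.
#' @param B number of bootstrap iterations (default 200).
#' @param seed master seed.
#' @param k_max,gain,delta,fpr_cap panel-selection parameters (see
#'   [build_panel()]).
#' @param fpr_target FPR at which out-of-bag sensitivity is reported.
#' @return A `resample_report`: per-iteration records, aggregate means with
#'   95% (2.5/97.5 percentile) intervals, and per-protein inclusion
#'   percentages.
#' @export
bootstrap_evaluate <- function(view, B = 200, seed = 1, k_max = 5,
                               gain = 0.01, delta = 0.10, fpr_cap = 0.5,
                               fpr_target = 0.10) {
  stopifnot(inherits(view, "interval_view"))
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  labels <- view$patients$label
  is_case <- as_case_indicator(labels)
  if (sum(is_case) < 5 || sum(!is_case) < 5)
    stop("need at least 5 patients per class", call. = FALSE)
  params <- list(k_max = k_max, gain = gain, delta = delta,
                 fpr_cap = fpr_cap, fpr_target = fpr_target)
  idx1 <- which(is_case)
  idx0 <- which(!is_case)
  iter_seeds <- derive_seeds(seed, B)
  n_redraws <- 0L
  iters <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(iter_seeds[b])
    repeat {
      train <- c(sample(idx1, length(idx1), replace = TRUE),
                 sample(idx0, length(idx0), replace = TRUE))
      test <- setdiff(seq_along(labels), train)
      if (any(is_case[test]) && any(!is_case[test])) break
      n_redraws <- n_redraws + 1L
    }
    iters[[b]] <- run_split(view$mom, labels, train, test, params)
  }
  new_resample_report("bootstrap", iters, view$panel, B, seed, params,
                      n_redraws)
}

#' Repeated stratified k-fold cross-validation of the selection pipeline
#'
#' `repeats` rounds of `folds`-fold cross-validation stratified by class
#' (fold sizes within a class differ by at most one patient, assigned
#' round-robin after shuffling) yield exactly `repeats * folds` train/test
#' pairs; the defaults 67 x 3 give 201 pairs. Each pair reruns the same
#' nested pipeline and aggregation as [bootstrap_evaluate()].
#'
#' @inheritParams bootstrap_evaluate
#' @param repeats number of cross-validation rounds (default 67).
#' @param folds folds per round (default 3).
#' @return A `resample_report` with `B = repeats * folds` iterations.
#' @export
repeated_cv_evaluate <- function(view, repeats = 67, folds = 3, seed = 1,
                                 k_max = 5, gain = 0.01, delta = 0.10,
                                 fpr_cap = 0.5, fpr_target = 0.10) {
  stopifnot(inherits(view, "interval_view"))
  labels <- view$patients$label
  is_case <- as_case_indicator(labels)
  if (sum(is_case) < folds || sum(!is_case) < folds)
    stop("each class must have at least `folds` patients", call. = FALSE)
  params <- list(k_max = k_max, gain = gain, delta = delta,
                 fpr_cap = fpr_cap, fpr_target = fpr_target)
  idx1 <- which(is_case)
  idx0 <- which(!is_case)
  rep_seeds <- derive_seeds(seed, repeats)
  iters <- vector("list", repeats * folds)
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    fold_of <- integer(length(labels))
    fold_of[sample(idx1)] <- rep_len(seq_len(folds), length(idx1))
    fold_of[sample(idx0)] <- rep_len(seq_len(folds), length(idx0))
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      iters[[(r - 1) * folds + f]] <-
        run_split(view$mom, labels, train, test, params)
    }
  }
  new_resample_report("repeated_cv", iters, view$panel,
                      repeats * folds, seed, params)
}

#' Per-protein panel inclusion frequencies
#'
#' @param report a `resample_report`.
#' @param min_pct reporting threshold in percent (default 10; boundary
#'   inclusive, so a protein selected in 20 of 200 iterations is listed).
#' @return data.frame `(protein, percent)` sorted by decreasing percentage.
#' @export
inclusion_frequencies <- function(report, min_pct = 10) {
  stopifnot(inherits(report, "resample_report"))
  out <- data.frame(protein = report$panel, percent = report$inclusion,
                    stringsAsFactors = FALSE)
  out <- out[out$percent >= min_pct, , drop = FALSE]
  out <- out[order(-out$percent, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-iteration substream seeds derived from one master seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
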