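# Empirical ROC curves, AUC, partial AUC over a false-positive-rate cap, and
# sensitivity at a fixed FPR. These metrics drive the marker ranking and the
# +0.01-pAUC panel acceptance rule, so they are implemented here rather than
# delegated; pROC serves as an independent cross-check in the test suite.

# achievable operating points of the empirical ROC: one point per distinct
# score threshold (predict case when score >= threshold), plus (0, 0).
# Tied case/control scores produce diagonal segments under trapezoidal
# interpolation.
roc_points <- function(scores, is_case) {
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  tp <- cumsum(is_case[o])
  fp <- cumsum(!is_case[o])
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(threshold = c(Inf, s[last_of_tie]),
             fpr = c(0, fp[last_of_tie] / n0),
             tpr = c(0, tp[last_of_tie] / n1))
}

#' ROC performance metrics for a risk score
#'
#' Computes the empirical ROC curve (ties handled by trapezoidal
#' interpolation), the AUC, the partial AUC restricted to false-positive
#' rates in `[0, fpr_cap]` (unnormalized, so it lies in `[0, fpr_cap]`), and
#' the sensitivity at the largest achievable empirical FPR not exceeding
#' `fpr_target` (a conservative step-function reading, so the achieved
#' specificity can exceed `1 - fpr_target`).
#'
#' @param scores numeric risk scores (higher = more case-like).
#' @param labels `"case"`/`"control"` vector (or logical case indicator)
#'   aligned with `scores`.
#' @param fpr_cap FPR cap for the partial AUC (default 0.5).
#' @param fpr_target FPR at which sensitivity is reported (default 0.10).
#' @return list with `auc`, `pauc`, `sensitivity_at_fpr`,
#'   `achieved_specificity`, `threshold`, `fpr_cap`, `fpr_target`.
#' @export
roc_metrics <- function(scores, labels, fpr_cap = 0.5, fpr_target = 0.10) {
  is_case <- as_case_indicator(labels)
  if (length(scores) != length(is_case))
    stop("scores and labels differ in length", call. = FALSE)
  if (!any(is_case) || all(is_case))
    stop("both classes must be present to compute ROC metrics", call. = FALSE)
  pts <- roc_points(scores, is_case)
  auc <- trapezoid_area(pts$fpr, pts$tpr, 1)
  pauc <- trapezoid_area(pts$fpr, pts$tpr, fpr_cap)
  ok <- which(pts$fpr <= fpr_target)
  at <- ok[pts$fpr[ok] == max(pts$fpr[ok])]
  at <- at[which.max(pts$tpr[at])]  # best TPR among points at that FPR
  list(auc = auc, pauc = pauc,
       sensitivity_at_fpr = pts$tpr[at],
       achieved_specificity = 1 - pts$fpr[at],
       threshold = pts$threshold[at],
       fpr_cap = fpr_cap, fpr_target = fpr_target)
}

# area under the piecewise-linear ROC from fpr = 0 to fpr = cap
trapezoid_area <- function(fpr, tpr, cap) {
  if (cap < max(fpr)) {
    # interpolate the curve at fpr = cap
    j <- which(fpr > cap)[1]
    if (fpr[j] == fpr[j - 1]) {
      tcap <- tpr[j - 1]
    } else {
      w <- (cap - fpr[j - 1]) / (fpr[j] - fpr[j - 1])
      tcap <- tpr[j - 1] + w * (tpr[j] - tpr[j - 1])
    }
    keep <- fpr <= cap
    fpr <- c(fpr[keep], cap)
    tpr <- c(tpr[keep], tcap)
  }
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("case", "control"))
    if (length(bad) > 0)
      stop("labels must be 'case'/'control'; got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    return(labels == "case")
  }
  if (is.numeric(labels)) return(labels == 1)
  stop("unsupported label type", call. = FALSE)
}
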