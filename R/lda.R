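# Two-class linear discriminant analysis with pooled within-class covariance
# and leave-one-patient-out cross-validated discriminant scores. Class priors
# do not affect ROC-based metrics, so the raw discriminant projection serves
# as the risk score. A small ridge (1e-8 * trace/p) keeps degenerate pooled
# covariances invertible (e.g. a constant feature inside a fold).

LDA_RIDGE <- 1e-8

lda_ridge <- function(S) {
  p <- ncol(S)
  lam <- LDA_RIDGE * sum(diag(S)) / p
  if (lam <= 0) lam <- LDA_RIDGE
  S + diag(lam, p)
}

#' Fit a two-class linear discriminant
#'
#' @param x numeric matrix (patients by features).
#' @param labels `"case"`/`"control"` (or logical case indicator).
#' @return list with `w` (weights), `b` (intercept); the score of a feature
#'   vector `v` is `v %*% w + b`, oriented so that higher scores are more
#'   case-like and the score is 0 at the midpoint of the class means.
#' @export
lda_fit <- function(x, labels) {
  x <- as.matrix(x)
  is_case <- as_case_indicator(labels)
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop("need at least 2 patients per class", call. = FALSE)
  x1 <- x[is_case, , drop = FALSE]
  x0 <- x[!is_case, , drop = FALSE]
  m1 <- colMeans(x1)
  m0 <- colMeans(x0)
  C1 <- crossprod(sweep(x1, 2, m1))
  C0 <- crossprod(sweep(x0, 2, m0))
  S <- lda_ridge((C1 + C0) / (nrow(x) - 2))
  w <- solve(S, m1 - m0)
  list(w = w, b = -sum((m1 + m0) / 2 * w))
}

#' Discriminant scores for new data
#'
#' @param fit result of [lda_fit()].
#' @param x feature matrix.
#' @return numeric score vector.
#' @export
lda_score <- function(fit, x) {
  drop(as.matrix(x) %*% fit$w) + fit$b
}

#' Leave-one-patient-out cross-validated discriminant scores
#'
#' For every patient `i`, a linear discriminant is fitted on all patients
#' except `i` and evaluated on `i`. Implemented with exact rank-one downdates
#' of the class means and pooled scatter (equivalent to refitting per fold).
#'
#' @param x numeric matrix (patients by features); one row per patient.
#' @param labels `"case"`/`"control"` vector.
#' @return numeric vector of out-of-fold scores, aligned with the rows of `x`.
#' @export
loocv_scores <- function(x, labels) {
  x <- as.matrix(x)
  is_case <- as_case_indicator(labels)
  n <- nrow(x)
  if (sum(is_case) < 3 || sum(!is_case) < 3)
    stop("need at least 3 patients per class for leave-one-out scores",
         call. = FALSE)
  m1 <- colMeans(x[is_case, , drop = FALSE])
  m0 <- colMeans(x[!is_case, , drop = FALSE])
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  C1 <- crossprod(sweep(x[is_case, , drop = FALSE], 2, m1))
  C0 <- crossprod(sweep(x[!is_case, , drop = FALSE], 2, m0))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i, ]
    if (is_case[i]) {
      d <- xi - m1
      m1i <- (m1 * n1 - xi) / (n1 - 1)
      C1i <- C1 - (n1 / (n1 - 1)) * tcrossprod(d)
      m0i <- m0; C0i <- C0
    } else {
      d <- xi - m0
      m0i <- (m0 * n0 - xi) / (n0 - 1)
      C0i <- C0 - (n0 / (n0 - 1)) * tcrossprod(d)
      m1i <- m1; C1i <- C1
    }
    S <- lda_ridge((C1i + C0i) / (n - 3))
    w <- solve(S, m1i - m0i)
    scores[i] <- sum(xi * w) - sum((m1i + m0i) / 2 * w)
  }
  scores
}

# Vectorized single-feature leave-one-patient-out discriminant scores for a
# whole protein matrix at once (the per-protein ranking step evaluates
# hundreds of proteins per resampling iteration). Column g equals
# loocv_scores(M[, g], labels) up to the same ridge.
loocv_scores_univariate <- function(M, labels) {
  M <- as.matrix(M)
  is_case <- as_case_indicator(labels)
  n <- nrow(M)
  n1 <- sum(is_case)
  n0 <- n - n1
  if (n1 < 3 || n0 < 3)
    stop("need at least 3 patients per class for leave-one-out scores",
         call. = FALSE)
  s1 <- colSums(M[is_case, , drop = FALSE])
  s0 <- colSums(M[!is_case, , drop = FALSE])
  m1 <- s1 / n1
  m0 <- s0 / n0
  C1 <- colSums(M[is_case, , drop = FALSE]^2) - n1 * m1^2
  C0 <- colSums(M[!is_case, , drop = FALSE]^2) - n0 * m0^2
  out <- matrix(NA_real_, n, ncol(M), dimnames = dimnames(M))
  # left-out case patients: downdate the case mean and scatter (1 x p rows
  # vectorized over proteins)
  idx1 <- which(is_case)
  X1 <- M[idx1, , drop = FALSE]
  m1i <- sweep(-X1, 2, s1, "+") / (n1 - 1)                    # means without i
  C1i <- sweep(-(n1 / (n1 - 1)) * sweep(X1, 2, m1)^2, 2, C1, "+")
  s2 <- sweep(C1i, 2, C0, "+") / (n - 3)
  s2 <- s2 + LDA_RIDGE * s2 + LDA_RIDGE * (s2 <= 0)
  w <- sweep(m1i, 2, m0) / s2
  out[idx1, ] <- (X1 - (m1i + rep(m0, each = nrow(X1))) / 2) * w
  # left-out control patients
  idx0 <- which(!is_case)
  X0 <- M[idx0, , drop = FALSE]
  m0i <- sweep(-X0, 2, s0, "+") / (n0 - 1)
  C0i <- sweep(-(n0 / (n0 - 1)) * sweep(X0, 2, m0)^2, 2, C0, "+")
  s2 <- sweep(C0i, 2, C1, "+") / (n - 3)
  s2 <- s2 + LDA_RIDGE * s2 + LDA_RIDGE * (s2 <= 0)
  w <- (rep(m1, each = nrow(X0)) - m0i) / s2
  out[idx0, ] <- (X0 - (m0i + rep(m1, each = nrow(X0))) / 2) * w
  out
}
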