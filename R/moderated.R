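# Covariate-adjusted per-protein linear models on log2 MoM with
# empirical-Bayes moderated t-statistics. The variance shrinkage is the
# classic scaled-inverse-chi-square hierarchical model: the prior degrees of
# freedom d0 and prior variance s0^2 are estimated by matching the first two
# moments of the log sample variances against their digamma/trigamma
# expressions, and each protein's variance is replaced by the posterior blend
# s2_post = (d0 s0^2 + d s2) / (d0 + d). Implemented here in closed form (the
# one externally-cited method this pipeline embodies); limma is used only as
# an independent cross-check in the test suite.

#' Newton inversion of the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0`.
#'
#' @param x positive values.
#' @return `y` with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (xi > 0) 0 else Inf)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (it in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes variance shrinkage
#'
#' Fits the scaled inverse-chi-square prior `s0^2, d0` to per-protein
#' residual variances `s2` on `df` degrees of freedom by moment matching of
#' `log(s2)`, and returns the posterior (moderated) variances.
#'
#' @param s2 per-protein residual sample variances.
#' @param df residual degrees of freedom (scalar; the same design is used for
#'   every protein).
#' @return list with `d0` (prior df; `Inf` when the sample variances are less
#'   dispersed than chi-square sampling noise alone), `s02` (prior variance)
#'   and `s2_post` (moderated variances).
#' @export
squeeze_variances <- function(s2, df) {
  stopifnot(length(df) == 1, df > 0)
  G <- length(s2)
  if (G < 2) stop("need at least 2 proteins to pool variances", call. = FALSE)
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  # excess dispersion of log variances over the chi-square sampling noise
  v <- mean((e - ebar)^2 * length(e) / (length(e) - 1) - trigamma(df / 2))
  if (v <= 0) {
    d0 <- Inf
    s02 <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(v)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, G) else (d0 * s02 + df * s2) / (d0 + df)
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Signed linear fold change
#'
#' Maps a log2 MoM difference `beta` (cases minus controls) to the signed
#' linear fold-change convention: `2^beta` when `beta >= 0`, else
#' `-2^(-beta)`, so negative values denote lower levels in cases.
#'
#' @param beta log2 MoM difference(s).
#' @return Signed linear fold change(s).
#' @export
signed_fold_change <- function(beta) {
  stopifnot(all(is.finite(beta)))
  ifelse(beta >= 0, 2^beta, -(2^(-beta)))
}

#' Covariate-adjusted moderated-t differential abundance
#'
#' For every protein in an interval view, ordinary least squares of log2 MoM
#' on group (case vs control) plus BMI, smoking status, maternal age and
#' nulliparity; residual variances are pooled across the interval's proteins
#' by [squeeze_variances()]; the moderated t-statistic `beta / (s_post *
#' sqrt(v))` is referred to a t distribution on `d0 + d` degrees of freedom;
#' Benjamini-Hochberg q-values are computed within the interval's protein
#' family (each interval x contrast analysis is one family).
#'
#' When `covariates` is `NULL` or incomplete for the view's patients, the
#' model degrades to the unadjusted group comparison with a warning.
#'
#' @param view an `interval_view` in linear MoM space.
#' @param covariates per-patient data.frame (`ID, BMI, Smoking, MaternalAge,
#'   Nulliparity`) or `NULL`.
#' @param alpha_q significance threshold on the q-value (default 0.1).
#' @param d0,s02 optional prior overrides (mainly for calibration studies);
#'   `d0 = Inf` fixes every variance at `s02`, `d0 = 0` gives the ordinary
#'   unmoderated t-test.
#' @return data.frame with one row per protein: `protein`, `logFC` (log2 MoM
#'   difference, cases - controls), `FC` (signed linear fold change), `s2`,
#'   `df`, `s2_post`, `t`, `p`, `q`, `significant`; attributes `d0`, `s02`,
#'   `adjusted`, `interval`, `mode`.
#' @export
fit_moderated <- function(view, covariates = NULL, alpha_q = 0.1,
                          d0 = NULL, s02 = NULL) {
  stopifnot(inherits(view, "interval_view"))
  labels <- view$patients$label
  is_case <- as_case_indicator(labels)
  if (!any(is_case) || all(is_case))
    stop("both groups must be present", call. = FALSE)
  Y <- log2(view$mom)
  n <- nrow(Y)
  design <- cbind(intercept = 1, group = as.numeric(is_case))
  adjusted <- FALSE
  if (!is.null(covariates)) {
    m <- match(view$patients$patient, covariates$ID)
    cv <- covariates[m, c("BMI", "Smoking", "MaternalAge", "Nulliparity")]
    if (anyNA(m) || anyNA(cv)) {
      warning("covariates missing for some patients; ",
              "falling back to the unadjusted group comparison",
              call. = FALSE)
    } else {
      design <- cbind(design, as.matrix(cv))
      adjusted <- TRUE
    }
  } else {
    warning("no covariate table supplied; group comparison is unadjusted",
            call. = FALSE)
  }
  if (n <= ncol(design))
    stop("fewer observations than model parameters", call. = FALSE)
  fit <- lm.fit(design, Y)
  if (fit$rank < ncol(design))
    stop("rank-deficient design (collinear covariates)", call. = FALSE)
  df <- n - fit$rank
  if (df < 1) stop("zero residual degrees of freedom", call. = FALSE)
  beta <- fit$coefficients["group", ]
  res <- as.matrix(fit$residuals)
  s2 <- colSums(res^2) / df
  R <- qr.R(fit$qr)
  xtxi <- chol2inv(R)
  piv <- fit$qr$pivot
  v_group <- xtxi[which(piv == 2), which(piv == 2)]  # unscaled var of group
  if (is.null(d0) != is.null(s02) && !(isTRUE(d0 == 0) && is.null(s02)))
    stop("override d0 and s02 together (s02 may be omitted only for d0 = 0)",
         call. = FALSE)
  if (is.null(d0)) {
    sq <- squeeze_variances(s2, df)
  } else if (d0 == 0) {
    sq <- list(d0 = 0, s02 = if (is.null(s02)) NA_real_ else s02,
               s2_post = s2)
  } else {
    s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
      (d0 * s02 + df * s2) / (d0 + df)
    sq <- list(d0 = d0, s02 = s02, s2_post = s2_post)
  }
  tstat <- beta / sqrt(sq$s2_post * v_group)
  df_total <- sq$d0 + df
  p <- 2 * pt(-abs(tstat), df = df_total)
  q <- bh_qvalues(p)
  out <- data.frame(protein = view$panel, logFC = unname(beta),
                    FC = signed_fold_change(unname(beta)),
                    s2 = unname(s2), df = df,
                    s2_post = unname(sq$s2_post),
                    t = unname(tstat), p = unname(p), q = unname(q),
                    significant = unname(q < alpha_q),
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- sq$d0
  attr(out, "s02") <- sq$s02
  attr(out, "adjusted") <- adjusted
  attr(out, "interval") <- view$interval
  attr(out, "mode") <- view$mode
  out
}
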