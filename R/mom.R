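# Multiples-of-the-mean (MoM) normalization: outlier thresholding, log2
# transform, gestational-age reference curves from cubic-spline linear
# mixed-effects models fitted on the control group, and conversion of all
# samples to MoM space.

#' Threshold outlier abundances
#'
#' Values larger than twice the 98th percentile of all samples are reset to
#' that ceiling (data thresholding). The percentile uses the default
#' linear-interpolation quantile estimator. The ceiling is recorded so the
#' identical rule can be replayed on new data.
#'
#' @param values nonnegative abundance vector over all samples of one protein.
#' @param ceiling optional precomputed ceiling; when `NULL` it is computed as
#'   `2 * quantile(values, 0.98)`.
#' @return list with `values` (clipped) and `ceiling`.
#' @export
clip_outliers <- function(values, ceiling = NULL) {
  stopifnot(length(values) >= 2, all(values >= 0, na.rm = TRUE))
  if (is.null(ceiling))
    ceiling <- 2 * unname(quantile(values, 0.98, na.rm = TRUE))
  if (ceiling == 0)
    warning("degenerate protein: all values zero (ceiling 0)", call. = FALSE)
  list(values = pmin(values, ceiling), ceiling = ceiling)
}

# cubic regression spline basis with 3 interior knots at GA quantiles;
# prediction GA is clamped to the boundary range
spline_basis <- function(ga, knots, boundary) {
  ga <- pmin(pmax(ga, boundary[1]), boundary[2])
  cbind(1, splines::bs(ga, knots = knots, degree = 3,
                       Boundary.knots = boundary))
}

#' Fit gestational-age reference curves on the control group
#'
#' For each protein, abundances are thresholded ([clip_outliers()], ceilings
#' computed over *all* samples of the cohort), log2 transformed, and the
#' control samples are modeled as a cubic regression spline in gestational
#' age (3 interior knots at the 25/50/75% quantiles of control sample GA,
#' boundary knots at the observed control GA range) with a per-patient random
#' intercept, fitted by REML with \pkg{lme4}. The fixed-effect curve is the
#' gestational-age reference mean; the random-intercept variance `tau2` and
#' residual variance `sigma2` are retained.
#'
#' Proteins whose mixed-model fit fails (e.g. constant abundance) fall back
#' to an ordinary least-squares spline fit (or an intercept-only mean) with a
#' warning, with `tau2 = 0`.
#'
#' @param cohort a [cohort_table()] on the raw scale. Control samples are the
#'   rows of patients with `EarlyPE == 0` (and `LatePE == 0` when present).
#' @return A `reference_curves` object: knots, boundary, per-protein
#'   coefficients, `tau2`, `sigma2`, clip ceilings and the panel.
#' @export
fit_reference_curves <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (cohort$scale != "raw")
    stop("reference curves are fitted on raw-scale abundances", call. = FALSE)
  meta <- cohort$meta
  is_ctrl <- meta$EarlyPE != 1 &
    (if ("LatePE" %in% names(meta)) meta$LatePE != 1 else TRUE)
  if (length(unique(meta$ID[is_ctrl])) < 10)
    stop("need at least 10 control patients to fit reference curves",
         call. = FALSE)
  ceilings <- apply(cohort$abundance, 2, function(v)
    2 * unname(quantile(v, 0.98)))
  ga <- meta$GA[is_ctrl]
  pid <- factor(meta$ID[is_ctrl])
  boundary <- range(ga)
  knots <- unname(quantile(ga, c(0.25, 0.5, 0.75)))
  X <- spline_basis(ga, knots, boundary)
  q <- ncol(X)
  G <- length(cohort$panel)
  coefs <- matrix(NA_real_, q, G, dimnames = list(NULL, cohort$panel))
  tau2 <- sigma2 <- setNames(numeric(G), cohort$panel)
  log2y <- function(g) {
    v <- pmin(cohort$abundance[is_ctrl, g], ceilings[g])
    log2(pmax(v, .Machine$double.eps))
  }
  ols_fallback <- function(y) {
    f <- lm.fit(X, y)
    if (any(is.na(f$coefficients))) {
      b <- c(mean(y), rep(0, q - 1))
      s2 <- var(y)
    } else {
      b <- f$coefficients
      s2 <- sum(f$residuals^2) / max(1, f$df.residual)
    }
    list(beta = b, tau2 = 0, sigma2 = max(s2, .Machine$double.eps))
  }
  dd <- data.frame(pid = pid)
  dd$X <- X
  base_fit <- NULL
  make_base_fit <- function(y) {
    dd$y <- y
    tryCatch(
      suppressMessages(lme4::lmer(y ~ 0 + X + (1 | pid), data = dd,
                                  REML = TRUE,
                                  control = lme4::lmerControl(calc.derivs = FALSE))),
      error = function(e) NULL)
  }
  extract <- function(fit) {
    vc <- lme4::VarCorr(fit)
    list(beta = unname(lme4::fixef(fit)),
         tau2 = as.numeric(vc$pid),
         sigma2 = attr(vc, "sc")^2)
  }
  n_fallback <- 0L
  for (g in seq_len(G)) {
    y <- log2y(g)
    res <- NULL
    if (sd(y) > 1e-10) {
      if (is.null(base_fit)) base_fit <- make_base_fit(y)
      if (!is.null(base_fit))
        res <- tryCatch(
          extract(suppressMessages(suppressWarnings(
            lme4::refit(base_fit, newresp = y)))),
          error = function(e) NULL)
    }
    if (is.null(res) || any(!is.finite(res$beta)) || res$sigma2 <= 0) {
      res <- ols_fallback(y)
      n_fallback <- n_fallback + 1L
    }
    coefs[, g] <- res$beta
    tau2[g] <- res$tau2
    sigma2[g] <- res$sigma2
  }
  if (n_fallback > 0)
    warning(n_fallback, " protein(s) fell back to ordinary spline ",
            "least squares (singular mixed-model fit)", call. = FALSE)
  structure(list(panel = cohort$panel, knots = knots, boundary = boundary,
                 coefficients = coefs, tau2 = tau2, sigma2 = sigma2,
                 ceilings = ceilings),
            class = "reference_curves")
}

#' Evaluate reference mean curves
#'
#' @param curves a `reference_curves` object from [fit_reference_curves()].
#' @param ga_weeks gestational ages (weeks); values outside the fitted range
#'   are clamped to the range boundary with a warning.
#' @param proteins protein identifiers (default: the whole panel).
#' @return Matrix of log2-scale reference means, `length(ga_weeks)` rows by
#'   `length(proteins)` columns.
#' @export
predict_reference <- function(curves, ga_weeks, proteins = curves$panel) {
  missing_p <- setdiff(proteins, curves$panel)
  if (length(missing_p) > 0)
    stop("protein(s) absent from the reference curves: ",
         paste(head(missing_p, 5), collapse = ", "), call. = FALSE)
  if (any(ga_weeks < curves$boundary[1] | ga_weeks > curves$boundary[2]))
    warning("gestational age outside the fitted range; clamped to boundary",
            call. = FALSE)
  X <- spline_basis(ga_weeks, curves$knots, curves$boundary)
  X %*% curves$coefficients[, proteins, drop = FALSE]
}

#' Convert a cohort to multiples-of-the-mean (MoM) space
#'
#' Each abundance is thresholded with the stored ceiling, log2 transformed
#' and divided (on the log scale: subtracted) by the gestational-age
#' reference mean for the same protein: `MoM = 2^(log2(clipped) - mu(GA))`.
#' The reference is a geometric mean fitted on controls only and frozen; case
#' samples never influence it.
#'
#' @param cohort a raw-scale [cohort_table()].
#' @param curves a `reference_curves` object fitted on the same panel.
#' @return A [cohort_table()] with `scale = "mom"` whose abundance matrix
#'   holds linear-scale MoM values.
#' @export
to_mom <- function(cohort, curves) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(curves, "reference_curves"))
  missing_p <- setdiff(cohort$panel, curves$panel)
  if (length(missing_p) > 0)
    stop("protein(s) absent from the reference curves: ",
         paste(head(missing_p, 5), collapse = ", "), call. = FALSE)
  clipped <- pmin(cohort$abundance,
                  rep(curves$ceilings[cohort$panel],
                      each = nrow(cohort$abundance)))
  mu <- predict_reference(curves, cohort$meta$GA, cohort$panel)
  mom <- 2^(log2(pmax(clipped, .Machine$double.eps)) - mu)
  out <- cohort
  out$abundance <- mom
  out$scale <- "mom"
  out
}

#' Serialize reference curves to JSON
#'
#' @param curves a `reference_curves` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(curves, path) {
  doc <- list(format = "pepanel_reference_curves", version = 1L,
              panel = curves$panel, knots = curves$knots,
              boundary = curves$boundary,
              coefficients = curves$coefficients,
              tau2 = curves$tau2, sigma2 = curves$sigma2,
              ceilings = curves$ceilings)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read reference curves from JSON
#'
#' @param path path written by [write_reference()].
#' @return A `reference_curves` object.
#' @export
read_reference <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pepanel_reference_curves"))
    stop("not a reference-curves document: ", path, call. = FALSE)
  co <- as.matrix(doc$coefficients)
  colnames(co) <- doc$panel
  structure(list(panel = doc$panel, knots = doc$knots,
                 boundary = doc$boundary, coefficients = co,
                 tau2 = setNames(doc$tau2, doc$panel),
                 sigma2 = setNames(doc$sigma2, doc$panel),
                 ceilings = setNames(doc$ceilings, doc$panel)),
            class = "reference_curves")
}
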