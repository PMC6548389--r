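# Synthetic longitudinal case-control cohort generator. Emulates the study
# conditions the pipeline assumes -- 33 early-preeclampsia cases / 90 normal
# pregnancies, prenatal visits every ~4 weeks from ~9 weeks of gestation with
# 2-6 profiled samples per patient, case diagnosis between 24.6 and 33.4
# weeks, per-protein smooth gestational-age baselines with subject random
# intercepts -- and plants interval-localized log2 MoM shifts on a marker
# subset, recording the ground truth (true markers, true shifts, closed-form
# oracle AUCs) for calibration and recovery checks.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the emulated study conditions. Effects enter additively on
#' the log2 abundance over the gestational-age baseline (i.e. directly on the
#' log2 MoM scale); a planted marker's shift ramps linearly from `onset`
#' gestational age to full size over `ramp` weeks, so effects can grow with
#' gestation as late-diverging trajectories do. Subject-level variation is a
#' random intercept with sd `tau`; within-subject noise has sd `sigma` (log2
#' units).
#'
#' @param n_cases,n_controls,n_late patients per group (late-preeclampsia
#'   patients are generated only when `n_late > 0`).
#' @param n_proteins panel size.
#' @param enrol_range uniform range of enrolment GA (weeks).
#' @param visit_interval,visit_jitter_sd scheduled inter-visit gap (weeks)
#'   and Gaussian jitter sd.
#' @param samples_range range of profiled samples per patient; a patient's
#'   profiled samples are a random subset of her visit schedule.
#' @param diag_range uniform range of case diagnosis GA (weeks).
#' @param control_delivery_mean,control_delivery_sd delivery GA distribution
#'   for unaffected pregnancies.
#' @param tau,sigma subject random-intercept and residual sds (log2 units).
#' @param markers data.frame `(protein, shift, onset, ramp)` of planted
#'   markers; `NULL` plants nothing (a global-null cohort).
#' @param mvm_count,severe_count cases flagged with placental
#'   maternal-vascular-malperfusion lesions / severe disease.
#' @param mvm_multiplier,severe_multiplier effect multipliers for flagged
#'   cases (1 = subgroups share the common case effect).
#' @param late_multiplier effect multiplier for late-preeclampsia patients.
#' @param covariate_coefs named coefficients (log2 units per sd of the
#'   covariate) of BMI, Smoking, MaternalAge, Nulliparity on every protein;
#'   all zero by default (non-confounded), nonzero values give a confounded
#'   preset for testing covariate adjustment.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_cases = 33, n_controls = 90, n_late = 0,
                         n_proteins = 200,
                         enrol_range = c(8, 12),
                         visit_interval = 4, visit_jitter_sd = 0.5,
                         samples_range = c(2, 6),
                         diag_range = c(24.6, 33.4),
                         control_delivery_mean = 39.5,
                         control_delivery_sd = 1,
                         tau = 0.3, sigma = 0.4,
                         markers = default_markers(n_proteins),
                         mvm_count = round(24 / 33 * n_cases),
                         severe_count = round(23 / 33 * n_cases),
                         mvm_multiplier = 1, severe_multiplier = 1,
                         late_multiplier = 0.5,
                         covariate_coefs = c(BMI = 0, Smoking = 0,
                                             MaternalAge = 0,
                                             Nulliparity = 0)) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls, n_late = n_late,
              n_proteins = n_proteins, enrol_range = enrol_range,
              visit_interval = visit_interval,
              visit_jitter_sd = visit_jitter_sd,
              samples_range = samples_range, diag_range = diag_range,
              control_delivery_mean = control_delivery_mean,
              control_delivery_sd = control_delivery_sd,
              tau = tau, sigma = sigma, markers = markers,
              mvm_count = mvm_count, severe_count = severe_count,
              mvm_multiplier = mvm_multiplier,
              severe_multiplier = severe_multiplier,
              late_multiplier = late_multiplier,
              covariate_coefs = covariate_coefs)
  if (tau <= 0 || sigma <= 0)
    stop("tau and sigma must be positive", call. = FALSE)
  if (n_cases < 1 || n_controls < 1 || n_proteins < 1)
    stop("group sizes and panel size must be positive", call. = FALSE)
  if (mvm_count > n_cases || severe_count > n_cases)
    stop("subgroup counts cannot exceed the number of cases", call. = FALSE)
  if (diag_range[1] >= diag_range[2] || diag_range[2] >= 34)
    stop("case diagnosis range must be increasing and below 34 weeks",
         call. = FALSE)
  if (!is.null(markers)) {
    panel <- protein_names(n_proteins)
    if (!all(markers$protein %in% panel))
      stop("planted markers must be members of the panel", call. = FALSE)
    if (any(markers$ramp < 0) || any(markers$onset < 0))
      stop("marker onset and ramp must be nonnegative", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

protein_names <- function(n) sprintf("PROT%04d", seq_len(n))

# four planted markers with equal moderate shifts and staggered onsets, fully
# active from 20 weeks of gestation onward
default_markers <- function(n_proteins) {
  n <- min(4, n_proteins)
  data.frame(protein = protein_names(n_proteins)[seq_len(n)],
             shift = rep(1.0, n),
             onset = c(0, 10, 14, 16)[seq_len(n)],
             ramp = rep(4, n), stringsAsFactors = FALSE)
}

# fraction of the full shift active at gestational age ga
ramp_fraction <- function(ga, onset, ramp) {
  if (ramp <= 0) return(as.numeric(ga >= onset))
  pmin(1, pmax(0, (ga - onset) / ramp))
}

#' Closed-form oracle AUC of a marker effect
#'
#' For the two-Gaussian single-sample model (case shift `effect` on log2 MoM,
#' total per-sample variance `tau^2 + sigma^2` in each group), the AUC of the
#' optimal score is `Phi(effect / sqrt(2 (tau^2 + sigma^2)))`. For a panel of
#' independent markers, pass the Euclidean norm of the shift vector as
#' `effect`.
#'
#' @param effect log2 MoM shift (or norm of the shift vector).
#' @param tau subject random-intercept sd.
#' @param sigma residual sd.
#' @return The oracle AUC.
#' @export
oracle_auc <- function(effect, tau, sigma) {
  stopifnot(tau > 0, sigma > 0)
  pnorm(effect / sqrt(2 * (tau^2 + sigma^2)))
}

#' Generate a synthetic longitudinal proteomic cohort
#'
#' Raw abundances are `2^(baseline_g(GA) + b_i + effect_g(GA, group) + cov_i
#' + eps)` with `b_i ~ N(0, tau^2)` and `eps ~ N(0, sigma^2)`; per-protein
#' baselines are a mix of constant, linear and smooth log2-scale
#' gestational-age curves. Case samples taken at or after diagnosis are still
#' generated (flagged by `GADiagnosis`) so the downstream censoring path is
#' exercised, as post-diagnosis samples were drawn in the emulated study but
#' excluded from analysis.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list with `cohort` (a raw-scale [cohort_table()] with covariates
#'   attached) and `truth`: planted `markers`, `tau`, `sigma`, and
#'   `oracle_auc(interval, scheme)` giving the closed-form panel AUC of the
#'   active shifts at an interval's midpoint.
#' @export
generate_cohort <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  panel <- protein_names(config$n_proteins)
  n_pat <- config$n_cases + config$n_controls + config$n_late
  ids <- sprintf("PT%03d", seq_len(n_pat))
  group <- rep(c("early", "control", "late"),
               c(config$n_cases, config$n_controls, config$n_late))
  mvm <- severe <- rep(0L, n_pat)
  case_idx <- which(group == "early")
  mvm[sample(case_idx, config$mvm_count)] <- 1L
  severe[sample(case_idx, config$severe_count)] <- 1L
  diag_ga <- rep(NA_real_, n_pat)
  diag_ga[case_idx] <- runif(config$n_cases, config$diag_range[1],
                             config$diag_range[2])
  late_idx <- which(group == "late")
  if (length(late_idx) > 0)
    diag_ga[late_idx] <- runif(length(late_idx), 34, 39)
  delivery <- rnorm(n_pat, config$control_delivery_mean,
                    config$control_delivery_sd)
  delivery[case_idx] <- pmin(diag_ga[case_idx] + runif(config$n_cases, 0.2, 1),
                             33.9)
  if (length(late_idx) > 0)
    delivery[late_idx] <- diag_ga[late_idx] + runif(length(late_idx), 0, 1)

  # per-protein baseline curves on the log2 scale
  level <- runif(config$n_proteins, 8, 12)
  type <- sample(c("constant", "linear", "smooth"), config$n_proteins,
                 replace = TRUE, prob = c(0.4, 0.4, 0.2))
  slope <- ifelse(type == "linear", runif(config$n_proteins, -0.05, 0.05), 0)
  amp <- ifelse(type == "smooth", runif(config$n_proteins, 0.2, 0.5), 0)
  period <- runif(config$n_proteins, 25, 45)
  phase <- runif(config$n_proteins, 0, 2 * pi)
  baseline_at <- function(ga) {
    # length(ga) x n_proteins matrix
    outer(ga, slope) + rep(level, each = length(ga)) +
      rep(amp, each = length(ga)) *
        sin(outer(ga, 2 * pi / period) + rep(phase, each = length(ga)))
  }

  # covariates (per patient)
  covars <- data.frame(ID = ids,
                       BMI = rnorm(n_pat, 27, 5),
                       Smoking = rbinom(n_pat, 1, 0.2),
                       MaternalAge = rnorm(n_pat, 24, 4),
                       Nulliparity = rbinom(n_pat, 1, 0.35),
                       stringsAsFactors = FALSE)
  cc <- config$covariate_coefs
  cov_shift <- cc["BMI"] * (covars$BMI - 27) / 5 +
    cc["Smoking"] * covars$Smoking +
    cc["MaternalAge"] * (covars$MaternalAge - 24) / 4 +
    cc["Nulliparity"] * covars$Nulliparity

  # per-protein subject random intercepts (matching the per-protein mixed
  # model fitted downstream; proteins are conditionally independent)
  b_ig <- matrix(rnorm(n_pat * config$n_proteins, 0, config$tau),
                 n_pat, config$n_proteins)

  # effect multiplier per patient (0 for controls)
  eff_mult <- numeric(n_pat)
  eff_mult[case_idx] <- 1 *
    ifelse(mvm[case_idx] == 1, config$mvm_multiplier, 1) *
    ifelse(severe[case_idx] == 1, config$severe_multiplier, 1)
  eff_mult[late_idx] <- config$late_multiplier

  rows <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    ga <- runif(1, config$enrol_range[1], config$enrol_range[2])
    visits <- numeric(0)
    while (ga < delivery[i]) {
      visits <- c(visits, ga)
      ga <- ga + max(1, config$visit_interval +
                          rnorm(1, 0, config$visit_jitter_sd))
    }
    if (length(visits) == 0) visits <- delivery[i] - 0.5
    # profiled-sample counts skew low (most patients contribute 2-3 samples)
    counts <- seq(config$samples_range[1], config$samples_range[2])
    wt <- rev(seq_along(counts)) + 1
    n_keep <- min(length(visits), sample(counts, 1, prob = wt / sum(wt)))
    keep <- sort(sample(seq_along(visits), n_keep))
    rows[[i]] <- data.frame(ID = ids[i], GA = visits[keep],
                            GADiagnosis = diag_ga[i],
                            EarlyPE = as.integer(group[i] == "early"),
                            EarlyPE_MVM = mvm[i], EarlyPE_Severe = severe[i],
                            LatePE = as.integer(group[i] == "late"),
                            stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  if (config$n_late == 0) meta$LatePE <- NULL
  n_samp <- nrow(meta)
  pat_of <- match(meta$ID, ids)

  log2ab <- baseline_at(meta$GA) + b_ig[pat_of, , drop = FALSE] +
    cov_shift[pat_of] +
    matrix(rnorm(n_samp * config$n_proteins, 0, config$sigma),
           n_samp, config$n_proteins)
  if (!is.null(config$markers)) {
    for (k in seq_len(nrow(config$markers))) {
      mk <- config$markers[k, ]
      g <- match(mk$protein, panel)
      log2ab[, g] <- log2ab[, g] + eff_mult[pat_of] * mk$shift *
        ramp_fraction(meta$GA, mk$onset, mk$ramp)
    }
  }
  ab <- 2^log2ab
  colnames(ab) <- panel
  cohort <- cohort_table(meta, ab, covariates = covars)

  truth <- list(
    markers = config$markers, tau = config$tau, sigma = config$sigma,
    covariate_coefs = config$covariate_coefs, seed = seed,
    oracle_auc = function(interval, scheme = ga_intervals()) {
      if (is.null(config$markers)) return(0.5)
      mid <- scheme$midpoint[scheme$label == interval]
      if (length(mid) == 0) stop("unknown interval: ", interval)
      sh <- config$markers$shift *
        mapply(ramp_fraction, mid, config$markers$onset, config$markers$ramp)
      oracle_auc(sqrt(sum(sh^2)), config$tau, config$sigma)
    })
  list(cohort = cohort, truth = truth)
}
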