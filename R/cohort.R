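# Cohort container, file layout, gestational-age intervals, contrasts and
# one-sample-per-patient interval views.

META_COLS <- c("ID", "GA", "GADiagnosis", "EarlyPE", "EarlyPE_MVM", "EarlyPE_Severe")

#' Construct a longitudinal proteomic cohort table
#'
#' A `cohort_table` holds long-format repeated plasma samples: one row per
#' venipuncture, with patient identifier, gestational age (GA, decimal weeks)
#' at the blood draw, GA at preeclampsia diagnosis (NA for unaffected
#' patients), binary group flags and one abundance column per protein.
#'
#' @param meta data.frame with columns `ID`, `GA`, `GADiagnosis`, `EarlyPE`,
#'   `EarlyPE_MVM`, `EarlyPE_Severe` and optionally `LatePE`.
#' @param abundance numeric matrix, rows aligned with `meta`, one column per
#'   protein (column names are the protein identifiers).
#' @param covariates optional per-patient data.frame with columns `ID`, `BMI`,
#'   `Smoking`, `MaternalAge`, `Nulliparity`.
#' @param scale `"raw"` for relative fluorescence units, `"mom"` once
#'   converted to multiples of the mean (see [to_mom()]).
#' @return An object of class `cohort_table` with fields `meta`, `abundance`,
#'   `panel` (protein identifiers), `covariates`, `scale` and (after
#'   [define_contrast()]) `contrast`.
#' @export
cohort_table <- function(meta, abundance, covariates = NULL, scale = "raw") {
  stopifnot(is.data.frame(meta), is.matrix(abundance),
            nrow(meta) == nrow(abundance))
  abundance <- abundance[, , drop = FALSE]
  storage.mode(abundance) <- "double"
  obj <- structure(
    list(meta = meta, abundance = abundance,
         panel = colnames(abundance), covariates = covariates,
         scale = scale, contrast = NULL),
    class = "cohort_table")
  validate_cohort(obj)
}

validate_cohort <- function(x) {
  meta <- x$meta
  missing_cols <- setdiff(META_COLS, names(meta))
  if (length(missing_cols) > 0)
    stop("cohort is missing metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(colnames(x$abundance)) || length(x$panel) < 1)
    stop("cohort must contain at least one protein column", call. = FALSE)
  if (any(!is.finite(meta$GA)) || any(meta$GA <= 0))
    stop("GA must be positive and finite for every sample", call. = FALSE)
  if (anyDuplicated(meta[, c("ID", "GA")]) > 0) {
    bad <- meta[duplicated(meta[, c("ID", "GA")]), c("ID", "GA")]
    stop("duplicate (patient, GA) sample rows, e.g. patient ", bad$ID[1],
         " at GA ", bad$GA[1], call. = FALSE)
  }
  # flags constant within patient, subgroup flags imply early PE
  for (fl in c("EarlyPE", "EarlyPE_MVM", "EarlyPE_Severe")) {
    rng <- tapply(meta[[fl]], meta$ID, function(v) length(unique(v)))
    if (any(rng > 1))
      stop("group flag ", fl, " varies within a patient", call. = FALSE)
  }
  if (any(meta$EarlyPE_MVM == 1 & meta$EarlyPE != 1) ||
      any(meta$EarlyPE_Severe == 1 & meta$EarlyPE != 1))
    stop("MVM/severe subgroup flags require EarlyPE = 1", call. = FALSE)
  diag_pe <- if ("LatePE" %in% names(meta)) {
    meta$EarlyPE == 1 | meta$LatePE == 1
  } else meta$EarlyPE == 1
  if (any(!is.na(meta$GADiagnosis) & !diag_pe))
    stop("GADiagnosis present for a patient without a preeclampsia flag",
         call. = FALSE)
  # sort samples within patient by GA (stable across patients)
  ord <- order(match(meta$ID, unique(meta$ID)), meta$GA)
  x$meta <- meta[ord, , drop = FALSE]
  rownames(x$meta) <- NULL
  x$abundance <- x$abundance[ord, , drop = FALSE]
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  pat <- patients_of(x)
  cat("cohort_table: ", nrow(x$meta), " samples / ", nrow(pat),
      " patients / ", length(x$panel), " proteins (scale: ", x$scale, ")\n",
      sep = "")
  cat("  early PE: ", sum(pat$EarlyPE == 1),
      "  (MVM ", sum(pat$EarlyPE_MVM == 1),
      ", severe ", sum(pat$EarlyPE_Severe == 1), ")",
      if ("LatePE" %in% names(pat)) paste0("  late PE: ", sum(pat$LatePE == 1)),
      "  controls: ", sum(pat$EarlyPE != 1 &
                          (if ("LatePE" %in% names(pat)) pat$LatePE != 1 else TRUE)),
      "\n", sep = "")
  if (!is.null(x$contrast))
    cat("  contrast: ", attr(x$contrast, "mode"), " (",
        sum(x$contrast$label == "case"), " cases, ",
        sum(x$contrast$label == "control"), " controls)\n", sep = "")
  invisible(x)
}

# one row per patient, metadata collapsed
patients_of <- function(cohort) {
  meta <- cohort$meta
  first <- !duplicated(meta$ID)
  out <- meta[first, setdiff(names(meta), c("GA")), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a cohort file
#'
#' Reads the delimited cohort layout: header `ID, GA, GADiagnosis, EarlyPE,
#' EarlyPE_MVM, EarlyPE_Severe` (optionally `LatePE`) followed by one column
#' per protein. Empty strings or `NA` denote absent `GADiagnosis`.
#'
#' @param path path to the delimited text file.
#' @param sep field separator (default comma).
#' @param covariates_path optional path to a per-patient covariate file with
#'   columns `ID, BMI, Smoking, MaternalAge, Nulliparity`.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, sep = ",", covariates_path = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  missing_cols <- setdiff(META_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("cohort file is missing metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  meta_cols <- intersect(c(META_COLS, "LatePE"), names(df))
  prot_cols <- setdiff(names(df), meta_cols)
  if (length(prot_cols) == 0)
    stop("cohort file has no protein columns after the metadata columns",
         call. = FALSE)
  ab <- as.matrix(df[, prot_cols, drop = FALSE])
  if (!is.numeric(ab)) {
    bad <- which(!vapply(df[prot_cols], is.numeric, logical(1)))[1]
    col <- prot_cols[bad]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                   !is.na(df[[col]]))[1]
    stop("non-numeric abundance in column '", col, "', row ", row,
         call. = FALSE)
  }
  if (anyNA(ab)) {
    idx <- which(is.na(ab), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing abundance in column '",
         prot_cols[idx["col"]], "', row ", idx["row"], call. = FALSE)
  }
  meta <- df[, meta_cols, drop = FALSE]
  meta$GADiagnosis <- suppressWarnings(as.numeric(meta$GADiagnosis))
  covars <- if (!is.null(covariates_path)) read_covariates(covariates_path, sep)
  cohort_table(meta, ab, covariates = covars)
}

#' Write a cohort file
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  df <- cbind(cohort$meta, as.data.frame(cohort$abundance,
                                         check.names = FALSE))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Read a per-patient covariate table
#'
#' @param path delimited file with columns `ID, BMI, Smoking, MaternalAge,
#'   Nulliparity`.
#' @param sep field separator.
#' @return data.frame keyed by `ID`.
#' @export
read_covariates <- function(path, sep = ",") {
  cv <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("ID", "BMI", "Smoking", "MaternalAge", "Nulliparity")
  missing_cols <- setdiff(need, names(cv))
  if (length(missing_cols) > 0)
    stop("covariate file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cv
}

#' Write a per-patient covariate table
#'
#' @param covariates data.frame with columns `ID, BMI, Smoking, MaternalAge,
#'   Nulliparity`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path, sep = ",") {
  write.table(covariates, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gestational-age interval scheme
#'
#' The study windows samples into gestational-age intervals; the default
#' scheme is 8-16, 16.1-22, 22.1-28, 28.1-32 and 32.1-36 weeks. Membership is
#' half-open `(previous upper, upper]` with the first interval closed at 8,
#' so values in the typographic gaps (e.g. 16.05) join the upper interval:
#' the printed ".1" lower bounds are display precision of a continuous
#' variable. Interval midpoints (used for within-interval sample selection)
#' are computed from the printed bounds, e.g. (22.1 + 28) / 2 = 25.05.
#'
#' @param labels interval labels.
#' @param lower printed lower bounds (weeks).
#' @param upper upper bounds (weeks).
#' @return data.frame of class `ga_intervals` with a `midpoint` column.
#' @export
ga_intervals <- function(labels = c("8-16", "16.1-22", "22.1-28",
                                    "28.1-32", "32.1-36"),
                         lower = c(8, 16.1, 22.1, 28.1, 32.1),
                         upper = c(16, 22, 28, 32, 36)) {
  stopifnot(length(labels) == length(lower),
            length(lower) == length(upper))
  if (any(lower >= upper) || any(lower <= 0))
    stop("interval bounds must be positive with lower < upper", call. = FALSE)
  if (is.unsorted(upper, strictly = TRUE) ||
      any(lower[-1] < upper[-length(upper)]))
    stop("intervals must be non-overlapping and strictly increasing",
         call. = FALSE)
  structure(data.frame(label = labels, lower = lower, upper = upper,
                       midpoint = (lower + upper) / 2,
                       stringsAsFactors = FALSE),
            class = c("ga_intervals", "data.frame"))
}

#' Assign a gestational age to an interval
#'
#' @param ga_weeks gestational age(s) in decimal weeks.
#' @param scheme a [ga_intervals()] scheme.
#' @return Character vector of interval labels; `NA` when the GA falls
#'   outside every interval.
#' @export
assign_interval <- function(ga_weeks, scheme = ga_intervals()) {
  stopifnot(all(ga_weeks > 0))
  breaks <- c(scheme$lower[1], scheme$upper)
  idx <- findInterval(ga_weeks, breaks, left.open = TRUE)
  lab <- rep(NA_character_, length(ga_weeks))
  inside <- idx >= 1 & idx <= nrow(scheme)
  lab[inside] <- scheme$label[idx[inside]]
  lab[ga_weeks == breaks[1]] <- scheme$label[1]  # first interval closed at 8
  lab
}

#' Label patients as cases and controls for an analysis contrast
#'
#' Four contrast modes mirror the study's analyses: all early-preeclampsia
#' cases vs normal pregnancy (`all_early_pe`); only cases with placental
#' maternal-vascular-malperfusion lesions (`mvm_only`); only severe cases
#' (`severe_only`); and early preeclampsia vs the combined group of normal
#' pregnancies plus late-preeclampsia cases
#' (`early_vs_control_plus_late`). Subgroup modes drop the remaining early
#' cases ("excluded"); the combined mode labels late-PE patients as controls.
#'
#' @param cohort a [cohort_table()].
#' @param mode contrast mode (see above).
#' @return The cohort with a `contrast` field: data.frame `(patient, label)`
#'   with label in case/control/excluded.
#' @export
define_contrast <- function(cohort,
                            mode = c("all_early_pe", "mvm_only",
                                     "severe_only",
                                     "early_vs_control_plus_late")) {
  mode <- match.arg(mode)
  pat <- patients_of(cohort)
  has_late <- "LatePE" %in% names(pat)
  late <- if (has_late) pat$LatePE == 1 else rep(FALSE, nrow(pat))
  label <- rep("excluded", nrow(pat))
  if (mode == "early_vs_control_plus_late") {
    if (!has_late || !any(late))
      stop("contrast 'early_vs_control_plus_late' requires late-PE records",
           call. = FALSE)
    label[pat$EarlyPE == 1] <- "case"
    label[pat$EarlyPE != 1] <- "control"  # normal pregnancies + late PE
  } else {
    case_flag <- switch(mode,
      all_early_pe = pat$EarlyPE == 1,
      mvm_only     = pat$EarlyPE_MVM == 1,
      severe_only  = pat$EarlyPE_Severe == 1)
    label[case_flag] <- "case"
    label[pat$EarlyPE != 1 & !late] <- "control"
    if (!any(case_flag))
      warning("contrast '", mode, "' retains 0 cases", call. = FALSE)
  }
  cohort$contrast <- structure(
    data.frame(patient = pat$ID, label = label, stringsAsFactors = FALSE),
    mode = mode)
  cohort
}

#' Select one pre-diagnosis sample per patient in a gestational-age interval
#'
#' Implements the study's per-interval sampling: case samples taken at or
#' after the gestational age at diagnosis are censored (strict `GA <
#' GADiagnosis` is required); among a patient's remaining samples falling in
#' the interval, the one closest to the interval midpoint is kept (ties go to
#' the earlier sample); patients with no eligible sample are absent from the
#' view.
#'
#' @param cohort a [cohort_table()] labeled by [define_contrast()].
#' @param interval interval label from the scheme.
#' @param scheme a [ga_intervals()] scheme.
#' @return An `interval_view`: list with `interval`, `mode`, `patients`
#'   (data.frame patient/label/ga), `mom` (matrix of abundances on the
#'   cohort's scale, one row per retained patient) and `panel`.
#' @export
select_interval_view <- function(cohort, interval, scheme = ga_intervals()) {
  if (is.null(cohort$contrast))
    stop("cohort must be labeled with define_contrast() first", call. = FALSE)
  if (!interval %in% scheme$label)
    stop("unknown interval label: ", interval, call. = FALSE)
  row <- scheme[scheme$label == interval, ]
  meta <- cohort$meta
  lab <- setNames(cohort$contrast$label, cohort$contrast$patient)
  keep_pat <- lab[meta$ID] %in% c("case", "control")
  precensor <- is.na(meta$GADiagnosis) | meta$GA < meta$GADiagnosis
  in_int <- assign_interval(meta$GA, scheme) %in% interval
  elig <- which(keep_pat & precensor & in_int)
  if (length(elig) == 0) {
    sel <- integer(0)
  } else {
    dist <- abs(meta$GA[elig] - row$midpoint)
    # per patient: min distance, ties to the earlier sample (rows are
    # GA-sorted within patient, so the first minimum is the earlier one)
    sel <- unlist(lapply(split(seq_along(elig), meta$ID[elig]), function(ii) {
      elig[ii][which.min(dist[ii])]
    }), use.names = FALSE)
    sel <- sort(sel)
  }
  pats <- data.frame(patient = meta$ID[sel],
                     label = unname(lab[meta$ID[sel]]),
                     ga = meta$GA[sel], stringsAsFactors = FALSE)
  structure(list(interval = interval, mode = attr(cohort$contrast, "mode"),
                 patients = pats,
                 mom = cohort$abundance[sel, , drop = FALSE],
                 panel = cohort$panel, scale = cohort$scale),
            class = "interval_view")
}

#' @export
print.interval_view <- function(x, ...) {
  cat("interval_view [", x$interval, ", ", x$mode, "]: ",
      sum(x$patients$label == "case"), " cases / ",
      sum(x$patients$label == "control"), " controls / ",
      length(x$panel), " proteins\n", sep = "")
  invisible(x)
}

#' Summarize a cohort
#'
#' Group counts, per-patient pre-diagnosis sample count medians (the study's
#' descriptive statistic), diagnosis GA range and interval occupancy.
#'
#' @param cohort a [cohort_table()].
#' @param scheme a [ga_intervals()] scheme.
#' @return A list with `n_proteins`, `n_cases`, `n_controls`, `n_mvm`,
#'   `n_severe`, `n_late`, `median_prediag_samples_cases`,
#'   `median_prediag_samples_controls`, `diagnosis_ga_range` and
#'   `interval_occupancy`.
#' @export
cohort_summary <- function(cohort, scheme = ga_intervals()) {
  pat <- patients_of(cohort)
  meta <- cohort$meta
  has_late <- "LatePE" %in% names(pat)
  is_control <- pat$EarlyPE != 1 & (if (has_late) pat$LatePE != 1 else TRUE)
  prediag <- is.na(meta$GADiagnosis) | meta$GA < meta$GADiagnosis
  n_prediag <- tapply(prediag, meta$ID, sum)
  case_ids <- pat$ID[pat$EarlyPE == 1]
  ctrl_ids <- pat$ID[is_control]
  occ <- table(factor(assign_interval(meta$GA[prediag], scheme),
                      levels = scheme$label))
  list(
    n_proteins = length(cohort$panel),
    n_cases = length(case_ids),
    n_controls = length(ctrl_ids),
    n_mvm = sum(pat$EarlyPE_MVM == 1),
    n_severe = sum(pat$EarlyPE_Severe == 1),
    n_late = if (has_late) sum(pat$LatePE == 1) else 0L,
    median_prediag_samples_cases = median(n_prediag[case_ids]),
    median_prediag_samples_controls = median(n_prediag[ctrl_ids]),
    diagnosis_ga_range = range(pat$GADiagnosis[pat$EarlyPE == 1]),
    interval_occupancy = occ)
}
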