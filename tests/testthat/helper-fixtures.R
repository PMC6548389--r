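# Fixtures built in code: tiny hand-constructed cohorts, Gaussian interval
# views, and GMT files, so no data ships with the package.

# hand-written cohort: n_prot proteins, a few patients with known GA layouts
tiny_cohort <- function(n_prot = 3) {
  meta <- data.frame(
    ID = c("A", "A", "A", "B", "B", "C", "C", "D"),
    GA = c(10, 26, 27.5, 23, 27.9, 12, 30, 15),
    GADiagnosis = c(27, 27, 27, NA, NA, NA, NA, NA),
    EarlyPE = c(1, 1, 1, 0, 0, 0, 0, 0),
    EarlyPE_MVM = c(1, 1, 1, 0, 0, 0, 0, 0),
    EarlyPE_Severe = c(0, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  ab <- matrix(seq_len(nrow(meta) * n_prot) + 100, nrow(meta), n_prot,
               dimnames = list(NULL, paste0("P", seq_len(n_prot))))
  cohort_table(meta, ab)
}

# interval view with Gaussian log2 MoM features; the first `n_signal`
# proteins get a case shift of `shift` log2 units
gaussian_view <- function(n_case = 33, n_ctrl = 90, n_prot = 10,
                          n_signal = 1, shift = 1.5, sdev = 0.5,
                          seed = 1, interval = "22.1-28") {
  set.seed(seed)
  n <- n_case + n_ctrl
  lab <- rep(c("case", "control"), c(n_case, n_ctrl))
  x <- matrix(rnorm(n * n_prot, 0, sdev), n, n_prot,
              dimnames = list(NULL, sprintf("P%03d", seq_len(n_prot))))
  if (n_signal > 0)
    x[lab == "case", seq_len(n_signal)] <-
      x[lab == "case", seq_len(n_signal)] + shift
  structure(list(interval = interval, mode = "all_early_pe",
                 patients = data.frame(patient = sprintf("PT%03d", 1:n),
                                       label = lab,
                                       ga = runif(n, 22.1, 28),
                                       stringsAsFactors = FALSE),
                 mom = 2^x, panel = colnames(x), scale = "mom"),
            class = "interval_view")
}

write_tiny_gmt <- function(terms, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(terms), function(tm)
    paste(c(tm, "na", terms[[tm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}

# default end-to-end MoM view shared by several test files (built once)
shared_mom_env <- new.env()

default_mom_cohort <- function(seed = 7) {
  key <- paste0("mom", seed)
  if (is.null(shared_mom_env[[key]])) {
    gen <- generate_cohort(synth_config(), seed = seed)
    curves <- suppressWarnings(fit_reference_curves(gen$cohort))
    shared_mom_env[[key]] <- list(gen = gen, curves = curves,
                                  mom = to_mom(gen$cohort, curves))
  }
  shared_mom_env[[key]]
}
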