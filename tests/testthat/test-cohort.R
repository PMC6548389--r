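# Cohort I/O, interval assignment, contrasts and interval views.

test_that("cohort files round-trip and are validated on read", {
  co <- tiny_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(co2$meta$ID, co$meta$ID)
  expect_equal(co2$meta$GA, co$meta$GA)
  expect_equal(co2$meta$GADiagnosis, co$meta$GADiagnosis)
  expect_equal(co2$abundance, co$abundance, tolerance = 1e-12)
  expect_equal(co2$panel, co$panel)

  # schema errors name the offending column
  df <- utils::read.csv(path, check.names = FALSE)
  df$GADiagnosis <- NULL
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "GADiagnosis")

  # zero protein columns
  df <- utils::read.csv(path, check.names = FALSE)
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(df[, 1:6], p3, row.names = FALSE)
  expect_error(read_cohort(p3), "no protein columns")

  # non-numeric abundance names row and column
  df <- utils::read.csv(path, check.names = FALSE)
  df$P2 <- as.character(df$P2)
  df$P2[3] <- "oops"
  p4 <- tempfile(fileext = ".csv")
  utils::write.csv(df, p4, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(p4), "P2")

  # duplicate (patient, GA) rows
  df <- utils::read.csv(path, check.names = FALSE)
  p5 <- tempfile(fileext = ".csv")
  utils::write.csv(rbind(df, df[1, ]), p5, row.names = FALSE)
  expect_error(read_cohort(p5), "duplicate")
})

test_that("interval assignment is half-open with a closed first interval", {
  expect_equal(assign_interval(12.0), "8-16")
  expect_equal(assign_interval(16.0), "8-16")
  expect_equal(assign_interval(16.05), "16.1-22")  # gap joins upper interval
  expect_equal(assign_interval(8.0), "8-16")
  expect_equal(assign_interval(22.0), "16.1-22")
  expect_equal(assign_interval(22.1), "22.1-28")
  expect_equal(assign_interval(36.0), "32.1-36")
  expect_true(is.na(assign_interval(7.5)))
  expect_true(is.na(assign_interval(36.5)))
  expect_error(assign_interval(-1))
})

test_that("contrast modes label and subset patients consistently", {
  gen <- generate_cohort(synth_config(), seed = 42)
  co <- gen$cohort
  all_pe <- define_contrast(co, "all_early_pe")
  mvm <- define_contrast(co, "mvm_only")
  sev <- define_contrast(co, "severe_only")
  n_cases <- function(x) sum(x$contrast$label == "case")
  expect_equal(n_cases(all_pe), 33)
  expect_equal(n_cases(mvm), 24)
  expect_equal(n_cases(sev), 23)
  # subgroup cases are a subset of all early-PE cases; dropped cases excluded
  cases_of <- function(x) x$contrast$patient[x$contrast$label == "case"]
  expect_true(all(cases_of(mvm) %in% cases_of(all_pe)))
  expect_true(all(cases_of(sev) %in% cases_of(all_pe)))
  expect_equal(sum(mvm$contrast$label == "excluded"), 33 - 24)
  expect_equal(sum(all_pe$contrast$label == "control"), 90)

  # combined mode needs late-PE records
  expect_error(define_contrast(co, "early_vs_control_plus_late"), "late")
  gen2 <- generate_cohort(synth_config(n_late = 20), seed = 42)
  comb <- define_contrast(gen2$cohort, "early_vs_control_plus_late")
  expect_equal(n_cases(comb), 33)
  expect_equal(sum(comb$contrast$label == "control"), 110)

  # no flagged subgroup -> 0 cases and a warning
  meta <- tiny_cohort()$meta
  meta$EarlyPE_MVM <- 0
  co0 <- cohort_table(meta, tiny_cohort()$abundance)
  expect_warning(z <- define_contrast(co0, "mvm_only"), "0 cases")
  expect_equal(sum(z$contrast$label == "case"), 0)
})

test_that("interval views censor at diagnosis and pick the midpoint-closest sample", {
  co <- define_contrast(tiny_cohort(), "all_early_pe")
  # patient A: diagnosed 27.0, samples 26.0 and 27.5 in 22.1-28
  v <- select_interval_view(co, "22.1-28")
  expect_equal(v$patients$ga[v$patients$patient == "A"], 26.0)
  # patient B: 23.0 vs 27.9; |23.0 - 25.05| < |27.9 - 25.05|
  expect_equal(v$patients$ga[v$patients$patient == "B"], 23.0)
  # A absent from 28.1-32 (no pre-diagnosis sample there)
  v2 <- select_interval_view(co, "28.1-32")
  expect_false("A" %in% v2$patients$patient)
  # D (GA 15) absent from 22.1-28, present in 8-16
  expect_false("D" %in% v$patients$patient)
  expect_true("D" %in% select_interval_view(co, "8-16")$patients$patient)
  expect_error(select_interval_view(co, "40-44"), "unknown interval")
  expect_error(select_interval_view(tiny_cohort(), "8-16"), "define_contrast")
})

test_that("midpoint ties go to the earlier sample", {
  meta <- data.frame(ID = c("A", "A", "B", "B", "B"),
                     GA = c(24.05, 26.05, 9, 24, 26),
                     GADiagnosis = c(30, 30, NA, NA, NA),
                     EarlyPE = c(1, 1, 0, 0, 0),
                     EarlyPE_MVM = 0, EarlyPE_Severe = 0)
  ab <- matrix(1:10, 5, 2, dimnames = list(NULL, c("P1", "P2")))
  co <- define_contrast(cohort_table(meta, ab), "all_early_pe")
  v <- select_interval_view(co, "22.1-28")  # midpoint 25.05, both 1.0 away
  expect_equal(v$patients$ga[v$patients$patient == "A"], 24.05)
})

test_that("view invariants hold across generated cohorts", {
  for (s in 1:3) {
    gen <- generate_cohort(synth_config(n_proteins = 20), seed = s)
    co <- define_contrast(gen$cohort, "all_early_pe")
    diag_of <- with(unique(co$meta[, c("ID", "GADiagnosis")]),
                    setNames(GADiagnosis, ID))
    for (iv in ga_intervals()$label) {
      v <- select_interval_view(co, iv)
      expect_false(any(duplicated(v$patients$patient)))
      expect_true(all(v$patients$patient %in% co$meta$ID))
      cases <- v$patients[v$patients$label == "case", ]
      if (nrow(cases) > 0)
        expect_true(all(cases$ga < diag_of[cases$patient]))
      expect_true(all(assign_interval(v$patients$ga) == iv))
    }
  }
})

test_that("cohort summary reports group counts and sampling medians", {
  gen <- generate_cohort(synth_config(), seed = 7)
  s <- cohort_summary(gen$cohort)
  expect_equal(s$n_proteins, 200)
  expect_equal(s$n_cases, 33)
  expect_equal(s$n_controls, 90)
  expect_equal(s$n_mvm, 24)
  expect_equal(s$n_severe, 23)
  expect_gte(s$diagnosis_ga_range[1], 24.6)
  expect_lte(s$diagnosis_ga_range[2], 33.4)
  expect_true(s$median_prediag_samples_cases >= 2)
})
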