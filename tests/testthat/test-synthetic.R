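# Synthetic cohort generator and its ground-truth oracle.

test_that("generation is a pure function of the seed", {
  g1 <- generate_cohort(synth_config(n_proteins = 15), seed = 5)
  g2 <- generate_cohort(synth_config(n_proteins = 15), seed = 5)
  expect_identical(g1$cohort$meta, g2$cohort$meta)
  expect_identical(g1$cohort$abundance, g2$cohort$abundance)
  expect_identical(g1$cohort$covariates, g2$cohort$covariates)
  g3 <- generate_cohort(synth_config(n_proteins = 15), seed = 6)
  expect_false(identical(g1$cohort$abundance, g3$cohort$abundance))
})

test_that("default cohorts match the emulated study design", {
  gen <- generate_cohort(synth_config(), seed = 3)
  meta <- gen$cohort$meta
  pat <- meta[!duplicated(meta$ID), ]
  expect_equal(sum(pat$EarlyPE == 1), 33)
  expect_equal(sum(pat$EarlyPE == 0), 90)
  expect_equal(sum(pat$EarlyPE_MVM == 1), 24)
  expect_equal(sum(pat$EarlyPE_Severe == 1), 23)
  # diagnosis GA range and early delivery
  dg <- pat$GADiagnosis[pat$EarlyPE == 1]
  expect_true(all(dg >= 24.6 & dg <= 33.4))
  # visit spacing ~4 weeks
  gaps <- unlist(tapply(meta$GA, meta$ID, diff))
  expect_gt(median(gaps), 3)
  # 2-6 profiled samples per patient
  counts <- table(meta$ID)
  expect_true(all(counts >= 1 & counts <= 6))
  expect_gte(median(counts), 2)
  # post-diagnosis samples exist so the censoring path is exercised
  expect_gt(sum(!is.na(meta$GADiagnosis) & meta$GA >= meta$GADiagnosis), 0)
  # covariates cover every patient
  expect_setequal(gen$cohort$covariates$ID, pat$ID)
  # abundances positive on the raw scale
  expect_true(all(gen$cohort$abundance > 0))
})

test_that("invalid configurations fail before any sampling", {
  expect_error(synth_config(tau = 0), "positive")
  expect_error(synth_config(mvm_count = 40), "exceed")
  expect_error(synth_config(diag_range = c(30, 35)), "below 34")
  expect_error(synth_config(markers = data.frame(protein = "NOPE", shift = 1,
                                                 onset = 0, ramp = 0)),
               "panel")
})

test_that("the closed-form oracle AUC matches Monte Carlo", {
  expect_equal(oracle_auc(0, 0.3, 0.4), 0.5)
  expect_gt(oracle_auc(50, 0.3, 0.4), 1 - 1e-10)
  # effect 1.5, tau 0.3, sigma 0.4: Phi(1.5 / sqrt(2 * 0.25)) ~= 0.9831
  a <- oracle_auc(1.5, 0.3, 0.4)
  expect_equal(a, pnorm(1.5 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(round(a, 4), 0.9831)
  set.seed(30)
  n <- 1e6
  ctrl <- rnorm(n, 0, 0.5)
  case <- rnorm(n, 1.5, 0.5)
  expect_equal(a, mean(case > ctrl), tolerance = 2e-3)
})

test_that("interval oracle AUC accounts for marker onset ramps", {
  cfg <- synth_config()
  gen <- generate_cohort(cfg, seed = 2)
  # at 22.1-28 (midpoint 25.05) every default marker is fully active
  expect_equal(gen$truth$oracle_auc("22.1-28"),
               oracle_auc(sqrt(4), 0.3, 0.4), tolerance = 1e-12)
  # at 8-16 (midpoint 12) markers with onset 14/16 contribute nothing and
  # the onset-10 marker is halfway up its 4-week ramp
  sh <- c(1, 0.5, 0, 0)
  expect_equal(gen$truth$oracle_auc("8-16"),
               oracle_auc(sqrt(sum(sh^2)), 0.3, 0.4), tolerance = 1e-12)
  # null configuration: chance level
  gen0 <- generate_cohort(synth_config(markers = NULL), seed = 2)
  expect_equal(gen0$truth$oracle_auc("22.1-28"), 0.5)
})

test_that("planted marker shifts are realized in MoM space", {
  env <- default_mom_cohort()
  mom <- suppressWarnings(env$mom)
  vw <- select_interval_view(define_contrast(mom, "all_early_pe"), "22.1-28")
  x <- log2(vw$mom)
  is_case <- vw$patients$label == "case"
  d <- colMeans(x[is_case, , drop = FALSE]) -
    colMeans(x[!is_case, , drop = FALSE])
  markers <- env$gen$truth$markers$protein
  # every fully-active planted marker shows close to its planted shift
  expect_true(all(abs(d[markers] - 1.0) < 0.35))
  # null proteins stay near zero on average
  expect_lt(max(abs(d[setdiff(names(d), markers)])), 0.5)
  expect_lt(abs(mean(d[setdiff(names(d), markers)])), 0.05)
})

test_that("subgroup effect multipliers raise subgroup sensitivity", {
  # MVM cases carry a 1.8x larger marker shift; averaged over seeds, the
  # MVM-only contrast should detect cases more sensitively than the mixed
  # early-PE contrast
  sens <- vapply(19:21, function(s) {
    cfg <- synth_config(n_proteins = 40,
                        markers = data.frame(protein = "PROT0001",
                                             shift = 0.8, onset = 0,
                                             ramp = 0),
                        mvm_multiplier = 1.8)
    gen <- generate_cohort(cfg, seed = s)
    curves <- suppressWarnings(fit_reference_curves(gen$cohort))
    mom <- suppressWarnings(to_mom(gen$cohort, curves))
    v_all <- select_interval_view(define_contrast(mom, "all_early_pe"),
                                  "22.1-28")
    v_mvm <- select_interval_view(define_contrast(mom, "mvm_only"),
                                  "22.1-28")
    c(bootstrap_evaluate(v_all, B = 60, seed = 7)$aggregates$sensitivity$mean,
      bootstrap_evaluate(v_mvm, B = 60, seed = 7)$aggregates$sensitivity$mean)
  }, numeric(2))
  expect_gt(mean(sens[2, ]), mean(sens[1, ]))
})
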