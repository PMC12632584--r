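test_that("identical config and effects give byte-identical cohorts, in both modes", {
  for (mode in c("direct", "raw")) {
    cfg <- cohort_config(n_per_cell = 15, seed = 9, mode = mode)
    a <- simulate_cohort(cfg, effect_preset("full"))
    b <- simulate_cohort(cfg, effect_preset("full"))
    expect_identical(a, b)
  }
  cfg2 <- cohort_config(n_per_cell = 15, seed = 10)
  expect_false(identical(simulate_cohort(cfg2, "full")$biomarker_ratio,
                         simulate_cohort(cohort_config(n_per_cell = 15, seed = 11),
                                         "full")$biomarker_ratio))
})

test_that("cohort structure matches the configuration", {
  cells <- c(preclinical_female = 7, preclinical_male = 5, mci_female = 9, mci_male = 4)
  cfg <- cohort_config(cells = cells, n_visits = 4, seed = 2)
  co <- simulate_cohort(cfg, "full")
  expect_silent(validate_cohort(co))
  base <- co[co$visit == 0, ]
  expect_equal(nrow(base), sum(cells))
  expect_equal(sum(base$group == "preclinical" & base$sex == "female"), 7)
  expect_equal(sum(base$group == "MCI" & base$sex == "male"), 4)
  expect_true(all(table(co$pid) == 4))
  # preclinical AD requires biomarker positivity at baseline
  expect_true(all(base$biomarker_ratio[base$group == "preclinical"] >= cfg$cutpoint))
  expect_true(all(base$biomarker_positive[base$group == "preclinical"]))
})

test_that("direct mode keeps hidden truth columns, raw mode hides them", {
  cfg_d <- cohort_config(n_per_cell = 5, seed = 3, mode = "direct")
  cfg_r <- cohort_config(n_per_cell = 5, seed = 3, mode = "raw")
  d <- simulate_cohort(cfg_d, "full")
  r <- simulate_cohort(cfg_r, "full")
  truth_cols <- c("truth_intercept", "truth_biomarker_change", "truth_memory_change")
  expect_true(all(truth_cols %in% names(d)))
  expect_false(any(truth_cols %in% names(r)))
  expect_identical(d[names(r)], r[names(r)])  # same draws underneath
  expect_true(all(is.na(d$truth_memory_change[d$visit == 0])))
  expect_false(anyNA(d$truth_memory_change[d$visit > 0]))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_visits = 1), "at least two timepoints")
  expect_error(cohort_config(innovation_sd_biomarker = 0), "positive")
  expect_error(cohort_config(apoe_prev = 1.2), "probability")
  expect_error(cohort_config(cells = c(a = 1)), "must be named")
  expect_error(
    simulate_cohort(cohort_config(n_per_cell = 5),
                    true_effects(effect_preset("full")$beta, 0.1, -1)),
    "sigma2")
  # stratified effects need a single-group cohort
  expect_error(simulate_cohort(cohort_config(n_per_cell = 5), effect_preset("mci")),
               "single-group")
})

test_that("generated staging scores encode the intended actuarial labels", {
  cfg <- cohort_config(n_per_cell = 30, seed = 5, mode = "raw")
  co <- simulate_cohort(cfg, "full")
  base <- co[co$visit == 0, ]
  # z-score against the generating normative truth (not fitted norms)
  truth <- normative_truth()
  lab <- vapply(seq_len(nrow(base)), function(i) {
    flags <- vapply(staging_tests(), function(tst) {
      m <- truth[truth$test == tst, ]
      flag_impaired(z_score(base[[tst]][i], base$age_baseline[i], base$sex[i],
                            base$education[i], m))
    }, logical(1))
    classify_jak_bondi(flags, dementia = FALSE)
  }, character(1))
  expect_equal(lab == "MCI", base$group == "MCI")
})

test_that("reference sample self-normalizes and recovers generating coefficients", {
  ref <- simulate_reference(n = 20000, seed = 21)
  norms <- fit_norms(ref)
  truth <- normative_truth()
  for (tst in truth$test) {
    m <- norms[norms$test == tst, ]
    tr <- truth[truth$test == tst, ]
    # slope recovery in residual-SD units; OLS standard errors at n = 20,000
    # keep every scaled slope error well inside 0.05. The raw intercept
    # extrapolates to age = 0 so it is checked through the prediction at the
    # covariate mean instead.
    for (cf in c("coef_age", "coef_sex", "coef_edu")) {
      expect_lt(abs(m[[cf]] - tr[[cf]]) / tr$residual_sd, 0.05)
    }
    pred_at <- function(x) x$intercept + x$coef_age * 74 + x$coef_sex * 0.5 +
      x$coef_edu * 16
    expect_lt(abs(pred_at(m) - pred_at(tr)) / tr$residual_sd, 0.05)
    # integer rounding inflates the residual SD only marginally
    expect_lt(abs(m$residual_sd - tr$residual_sd) / tr$residual_sd, 0.05)
    z <- z_score(ref[[tst]], ref$age, ref$sex, ref$education, m)
    expect_lt(abs(mean(z)), 0.02)
    expect_lt(abs(stats::sd(z) - 1), 0.02)
  }
})

test_that("cohort CSV round-trips through write_cohort/read_cohort", {
  cfg <- cohort_config(n_per_cell = 4, seed = 12)
  co <- simulate_cohort(cfg, "null")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_match(readLines(path, n = 1), "# seed: 12", fixed = TRUE)
  back <- read_cohort(path)
  expect_equal(back$pid, co$pid)
  expect_equal(back$biomarker_ratio, co$biomarker_ratio, tolerance = 1e-12)
  expect_equal(back$truth_memory_change, co$truth_memory_change, tolerance = 1e-12)
})
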