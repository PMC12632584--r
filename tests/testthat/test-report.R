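test_that("identical sex groups give p-values of 1 everywhere", {
  cfg <- cohort_config(cells = c(preclinical_female = 10, preclinical_male = 0,
                                 mci_female = 10, mci_male = 0),
                       seed = 81, mode = "raw")
  co <- simulate_cohort(cfg, effect_preset("full"))
  # mirror every female participant as an identical male
  twin <- co
  twin$pid <- paste0(twin$pid, "m")
  twin$sex <- "male"
  both <- rbind(co, twin)
  tab <- suppressWarnings(baseline_table(both))
  expect_true(all(abs(tab$p - 1) < 1e-8))
  expect_true(all(abs(tab$statistic) < 1e-6))
})

test_that("the chi-square statistic matches the textbook closed form", {
  # APOE 50/50 among 100 females vs 80/20 among 100 males:
  # chi2 = N (ad - bc)^2 / (r1 r2 c1 c2) = 200 * (50*20 - 50*80)^2 / (100*100*130*70)
  mk <- function(sex, n, n_pos) {
    data.frame(pid = paste0(sex, seq_len(n)), visit = 0, sex = sex,
               group = "MCI", age_baseline = 70 + seq_len(n) %% 7,
               education = 14 + seq_len(n) %% 5,
               apoe4 = as.integer(seq_len(n) <= n_pos),
               biomarker_ratio = 0.03 + (seq_len(n) %% 10) / 500,
               ravlt_immediate = 30 + seq_len(n) %% 20,
               ravlt_delayed = 5 + seq_len(n) %% 8,
               tmt_a = 30, tmt_b = 80, category_fluency = 18, boston_naming = 25,
               ravlt_recognition = 12, biomarker_positive = TRUE, dementia = FALSE)
  }
  base <- rbind(mk("female", 100, 50), mk("male", 100, 80))
  fu <- base; fu$visit <- 1
  fu$ravlt_immediate <- pmax(fu$ravlt_immediate - 1, 0)
  fu$biomarker_ratio <- fu$biomarker_ratio + 0.001
  co <- rbind(base, fu)
  # the single-group design leaves a zero cell in the diagnostic-group table,
  # which warns; the APOE table under test has no zero cell
  tab <- suppressWarnings(baseline_table(co))
  hand <- 200 * (50 * 20 - 50 * 80)^2 / (100 * 100 * 130 * 70)
  expect_equal(tab$statistic[tab$variable == "apoe4_carrier"], hand,
               tolerance = 1e-10)
  expect_equal(hand, 19.78022, tolerance = 1e-6)
})

test_that("the generated female memory advantage is detected at cohort scale", {
  cfg <- cohort_config(n_per_cell = 100, seed = 82, mode = "raw")
  co <- simulate_cohort(cfg, effect_preset("full"))
  tab <- baseline_table(co)
  row <- tab[tab$variable == "baseline_memory_composite", ]
  expect_lt(row$p, 0.05)
  expect_gt(row$statistic, 0)  # female mean higher
})

test_that("welch statistic flips sign under label swap; chi-square does not change", {
  cfg <- cohort_config(n_per_cell = 30, seed = 83, mode = "raw")
  co <- simulate_cohort(cfg, effect_preset("full"))
  tab1 <- baseline_table(co)
  sw <- co
  sw$sex <- ifelse(co$sex == "female", "male", "female")
  tab2 <- baseline_table(sw)
  t1 <- tab1[tab1$variable == "age", ]
  t2 <- tab2[tab2$variable == "age", ]
  expect_equal(t1$statistic, -t2$statistic, tolerance = 1e-10)
  expect_equal(t1$p, t2$p, tolerance = 1e-10)
  c1 <- tab1[tab1$variable == "apoe4_carrier", ]
  c2 <- tab2[tab2$variable == "apoe4_carrier", ]
  expect_equal(c1$statistic, c2$statistic, tolerance = 1e-10)
})

test_that("a zero cell triggers the documented continuity fallback with a warning", {
  cfg <- cohort_config(cells = c(preclinical_female = 12, preclinical_male = 12,
                                 mci_female = 0, mci_male = 12),
                       seed = 84, mode = "raw")
  co <- simulate_cohort(cfg, effect_preset("full"))
  expect_warning(tab <- baseline_table(co), "continuity correction")
  expect_true(is.finite(tab$p[tab$variable == "mci_group"]))
})

test_that("the report bundle is structurally complete and byte-identical on rerun", {
  p <- make_small_pipeline()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(p$fit, d1, seed = 42)
  write_report(p$fit, d2, seed = 42)
  files <- c("baseline.csv", "change_scores.csv", "model_full.csv",
             "model_preclinical.csv", "model_mci.csv", "model_sensitivity.csv",
             "run_metadata.json", "summary.txt")
  expect_setequal(list.files(d1), files)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  meta <- jsonlite::read_json(file.path(d1, "run_metadata.json"))
  expect_equal(meta$seed, 42)
  expect_match(meta$config_hash, "^[0-9a-f]{32}$")
  full_tab <- utils::read.csv(file.path(d1, "model_full.csv"))
  expect_true(all(c("sigma2", "tau00_id", "icc") %in% full_tab$term))
})

test_that("a model that was not run is marked as such in the bundle", {
  cfg <- cohort_config(cells = c(preclinical_female = 0, preclinical_male = 0,
                                 mci_female = 25, mci_male = 25),
                       seed = 85, mode = "raw")
  co <- simulate_cohort(cfg, effect_preset("mci"))
  ref <- simulate_reference(600, 86)
  fit <- suppressWarnings(memdecline(co, reference = ref))
  d <- withr::local_tempdir()
  write_report(fit, d)
  full_tab <- utils::read.csv(file.path(d, "model_full.csv"))
  expect_equal(full_tab$term[1], "not run")
})
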