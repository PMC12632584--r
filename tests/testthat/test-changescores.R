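test_that("memory composite averages the two component z-scores", {
  s <- list(imm_mean = 40, imm_sd = 10, del_mean = 7, del_sd = 3)
  expect_equal(memory_composite(40, 7, s), 0)             # both at the means
  expect_equal(memory_composite(50, 4, s), 0)             # +1 and -1 average out
  expect_equal(memory_composite(50, 10, s), 1.0)          # +1 and +1
  expect_equal(memory_composite(c(40, 50), c(7, 10), s), c(0, 1))
  expect_true(is.na(memory_composite(NA, 7, s)))          # no single-component fallback
  expect_error(memory_composite(80, 7, s), "0-75")
  expect_error(memory_composite(40, 16, s), "0-15")
  expect_error(memory_composite(40, 7, list(imm_mean = 40, imm_sd = 0,
                                            del_mean = 7, del_sd = 3)), "positive")
})

test_that("lagged residuals match the closed-form OLS oracle on a 3-pair fixture", {
  # pairs (lag, value): (1,2), (2,3), (3,5); one pair per participant
  d <- data.frame(pid = rep(c("a", "b", "c"), each = 2),
                  visit = rep(0:1, 3),
                  v = c(1, 2, 2, 3, 3, 5))
  res <- lagged_residuals(d, "v")
  oracle <- ols_closed_form(x = c(1, 2, 3), y = c(2, 3, 5))
  expect_equal(attr(res, "slope"), oracle$slope)          # 1.5
  expect_equal(attr(res, "intercept"), oracle$intercept)  # 1/3
  expect_equal(oracle$slope, 1.5)
  expect_equal(oracle$intercept, 1 / 3)
  expect_equal(res$residual, oracle$residuals)
  expect_equal(res$residual, c(1 / 6, -1 / 3, 1 / 6))
  expect_equal(sum(res$residual), 0, tolerance = 1e-12)
})

test_that("a perfectly predictable series yields slope 1, intercept 0, zero residuals", {
  # constant within participant, different levels across participants
  d <- data.frame(pid = rep(c("a", "b", "c", "d"), each = 3),
                  visit = rep(0:2, 4),
                  v = rep(c(1, 4, 9, 2.5), each = 3))
  res <- lagged_residuals(d, "v")
  expect_equal(attr(res, "slope"), 1, tolerance = 1e-10)
  expect_equal(attr(res, "intercept"), 0, tolerance = 1e-10)
  expect_equal(res$residual, rep(0, 8), tolerance = 1e-10)
})

test_that("residuals obey the OLS normal equations and ignore row order", {
  cfg <- cohort_config(n_per_cell = 25, seed = 51, mode = "raw")
  co <- simulate_cohort(cfg, "full")
  res <- lagged_residuals(co, "biomarker_ratio")
  expect_equal(mean(res$residual), 0, tolerance = 1e-10)
  lagged <- co$biomarker_ratio[match(paste(res$pid, res$visit - 1),
                                     paste(co$pid, co$visit))]
  expect_equal(stats::cov(res$residual, lagged), 0, tolerance = 1e-10)
  # reordering input rows never changes any residual
  res2 <- lagged_residuals(co[rev(seq_len(nrow(co))), ], "biomarker_ratio")
  expect_equal(res2, res)
})

test_that("only literal lag-one pairs are used; missing endpoints are dropped and counted", {
  d <- data.frame(pid = rep("a", 5), visit = 0:4, v = c(1, 2, NA, 3, 5))
  d <- rbind(d, data.frame(pid = "b", visit = 0:4, v = c(2, 2.5, 3, 3.5, 4)))
  res <- lagged_residuals(d, "v")
  # pairs (1,2) and (2,3) of participant a both involve the missing visit 2
  expect_false(any(res$pid == "a" & res$visit %in% c(2, 3)))
  expect_equal(attr(res, "dropped"), 2)
  expect_equal(attr(res, "n_pairs"), 6)
  expect_error(lagged_residuals(data.frame(pid = c("a", "a"), visit = 0:1,
                                           v = c(1, 2)), "v"),
               "at least 3 usable")
  const <- data.frame(pid = rep(c("a", "b"), each = 3), visit = rep(0:2, 2), v = 5)
  expect_error(lagged_residuals(const, "v"), "constant")
})

test_that("lagged residuals remove the autocorrelation carried by the raw series", {
  # AR(1) series with known slope; residual lag-1 autocorrelation collapses to ~0
  set.seed(61)
  n <- 400; TT <- 6; phi <- 0.8
  v <- matrix(0, n, TT)
  v[, 1] <- rnorm(n)
  for (t in 2:TT) v[, t] <- phi * v[, t - 1] + rnorm(n, sd = 0.5)
  d <- data.frame(pid = rep(seq_len(n), each = TT), visit = rep(0:(TT - 1), n),
                  v = as.vector(t(v)))
  res <- lagged_residuals(d, "v")
  expect_equal(attr(res, "slope"), phi, tolerance = 0.05)
  raw_ac <- cor(as.vector(v[, -TT]), as.vector(v[, -1]))
  wide <- matrix(res$residual, nrow = n, byrow = TRUE)
  res_ac <- cor(as.vector(wide[, -(TT - 1)]), as.vector(wide[, -1]))
  expect_gt(raw_ac, 0.6)
  expect_lt(abs(res_ac), 0.08)
})

test_that("the change table joins change scores with baseline covariates", {
  cfg <- cohort_config(n_per_cell = 20, seed = 52, mode = "raw")
  co <- simulate_cohort(cfg, "full")
  tab <- build_change_table(co)
  expect_true(all(c("biomarker_change", "memory_change", "sex", "group",
                    "age_c", "edu_c", "apoe4") %in% names(tab)))
  expect_true(all(tab$visit >= 1))
  expect_equal(mean(tab$age_c[!duplicated(tab$pid)]), 0, tolerance = 1e-10)
  expect_setequal(unique(tab$sex), c(0, 1))
  # per-visit rows: n_visits - 1 change observations per participant
  expect_true(all(table(tab$pid) == cfg$n_visits - 1))
})
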