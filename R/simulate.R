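# Synthetic longitudinal cohorts with the structure the downstream analysis
# assumes: two baseline diagnostic groups (preclinical AD, MCI), annual
# visits, a CSF pTau181/Abeta42 ratio series, RAVLT-based memory scores, six
# staging tests, and a known change-on-change generative model.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a realistic early-AD observational cohort: age 74 +- 6.5
#' years, education 16 +- 2.7 years, APOE-e4 carrier prevalence 0.57, baseline
#' CSF pTau181/Abeta42 ratio 0.044 +- 0.028, five annual visits, biomarker
#' change innovations with SD 0.028 on the ratio scale.
#'
#' @param cells named integer vector of participant counts per sex x group
#'   cell, names `preclinical_female`, `preclinical_male`, `mci_female`,
#'   `mci_male`. Zero cells are allowed (single-group cohorts).
#' @param n_per_cell shorthand: a single count used for all four cells when
#'   `cells` is not given.
#' @param n_visits visits per participant (annual, gap-free); must be >= 2
#'   because change scores need at least two timepoints.
#' @param age_mean,age_sd baseline age distribution in years (truncated to
#'   55-88).
#' @param edu_mean,edu_sd education in years (truncated to 6-20).
#' @param apoe_prev APOE-e4 carrier probability.
#' @param ratio_baseline_mean,ratio_baseline_sd baseline biomarker ratio
#'   distribution (unitless, truncated at 0).
#' @param ar_slope,ar_intercept first-order autoregression used to build the
#'   raw biomarker series from its change innovations; the default intercept
#'   `(1 - ar_slope) * ratio_baseline_mean` keeps the series stationary around
#'   the baseline mean.
#' @param innovation_sd_biomarker SD of the per-visit biomarker change
#'   innovations (ratio units).
#' @param ar_slope_memory autoregressive slope of the observed memory series
#'   in component z-units; the default 0.7 matches the annual test-retest
#'   stability typical of list-learning scores (occasion-specific measurement
#'   error makes observed scores regress toward the mean even when the
#'   underlying change process is persistent).
#' @param cutpoint CSF ratio positivity cut-point (ratio at or above counts
#'   positive); a configurable convention, not an endorsed clinical value.
#' @param mode `"direct"` keeps the hidden truth columns (`truth_intercept`,
#'   `truth_biomarker_change`, `truth_memory_change`) so estimators can be
#'   checked against the generative model exactly; `"raw"` drops them so the
#'   full pipeline (staging, composite, lagged residuals) must recover change
#'   from the raw series.
#' @param sex_coding,group_coding indicator codings used when the generative
#'   fixed effects are applied (defaults female = 1, MCI = 1).
#' @param seed integer seed; identical `(config, effects, seed)` give
#'   byte-identical cohorts.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(cells = NULL, n_per_cell = 100, n_visits = 5,
                          age_mean = 74, age_sd = 6.5,
                          edu_mean = 16, edu_sd = 2.7,
                          apoe_prev = 0.57,
                          ratio_baseline_mean = 0.044, ratio_baseline_sd = 0.028,
                          ar_slope = 0.9,
                          ar_intercept = (1 - ar_slope) * ratio_baseline_mean,
                          innovation_sd_biomarker = 0.028,
                          ar_slope_memory = 0.7,
                          cutpoint = 0.025,
                          mode = c("direct", "raw"),
                          sex_coding = c(female = 1, male = 0),
                          group_coding = c(MCI = 1, preclinical = 0),
                          seed = 1L) {
  mode <- match.arg(mode)
  cell_names <- c("preclinical_female", "preclinical_male", "mci_female", "mci_male")
  if (is.null(cells)) {
    stopifnot_positive(n_per_cell, "n_per_cell")
    cells <- stats::setNames(rep(as.integer(n_per_cell), 4L), cell_names)
  }
  if (is.null(names(cells)) || !setequal(names(cells), cell_names)) {
    stop("cells must be named ", paste(cell_names, collapse = ", "), call. = FALSE)
  }
  cells <- cells[cell_names]
  if (any(cells < 0) || sum(cells) < 1) {
    stop("cell counts must be non-negative with at least one participant", call. = FALSE)
  }
  if (!is.numeric(n_visits) || n_visits < 2) {
    stop("n_visits must be >= 2: change scores need at least two timepoints",
         call. = FALSE)
  }
  for (nm in c("age_sd", "edu_sd", "ratio_baseline_sd", "innovation_sd_biomarker")) {
    stopifnot_positive(get(nm), nm)
  }
  stopifnot_scalar_prob(apoe_prev, "apoe_prev")
  if (!is.numeric(cutpoint) || cutpoint < 0) stop("cutpoint must be >= 0", call. = FALSE)
  sex_indicator("female", sex_coding)  # validates coding
  group_indicator("MCI", group_coding)
  structure(list(
    cells = cells, n_visits = as.integer(n_visits),
    age_mean = age_mean, age_sd = age_sd,
    edu_mean = edu_mean, edu_sd = edu_sd,
    apoe_prev = apoe_prev,
    ratio_baseline_mean = ratio_baseline_mean, ratio_baseline_sd = ratio_baseline_sd,
    ar_slope = ar_slope, ar_intercept = ar_intercept,
    innovation_sd_biomarker = innovation_sd_biomarker,
    ar_slope_memory = ar_slope_memory,
    cutpoint = cutpoint, mode = mode,
    sex_coding = sex_coding, group_coding = group_coding,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# baseline z-score draws that pin the actuarial label: MCI participants get
# both episodic-memory tests impaired with margin below the z = -1 rule;
# everyone else stays clear of the boundary so staging against estimated
# norms reproduces the generated labels.
draw_staging_z <- function(n, mci) {
  z <- matrix(NA_real_, n, 6, dimnames = list(NULL, .staging_tests))
  for (tst in .staging_tests) {
    z[, tst] <- rtruncnorm1(n, mean = 0.2, sd = 0.8, lower = -0.75)
  }
  n_mci <- sum(mci)
  if (n_mci) {
    z[mci, "ravlt_delayed"]     <- rtruncnorm1(n_mci, -1.8, 0.5, upper = -1.3)
    z[mci, "ravlt_recognition"] <- rtruncnorm1(n_mci, -1.8, 0.5, upper = -1.3)
  }
  z
}

norm_predict_truth <- function(test, age, sex_num, edu) {
  nt <- .normative_truth[.normative_truth$test == test, ]
  nt$intercept + nt$coef_age * age + nt$coef_sex * sex_num + nt$coef_edu * edu
}

score_range <- function(test) {
  switch(test,
    tmt_a = c(5, 300), tmt_b = c(10, 400),
    category_fluency = c(0, 60), boston_naming = c(0, 30),
    ravlt_delayed = c(0, 15), ravlt_recognition = c(0, 15),
    ravlt_immediate = c(0, 75)
  )
}

#' Generate a seeded synthetic longitudinal cohort
#'
#' Draws per-participant covariates and a random intercept `b_i ~
#' N(0, tau00)`, per-visit biomarker change innovations `u_it ~ N(0,
#' innovation_sd^2)`, and memory change values `y_it = x_it' beta + b_i +
#' e_it` with `e_it ~ N(0, sigma2)`, then reconstructs raw series: the
#' biomarker ratio as a first-order autoregression with innovations `u_it`,
#' and RAVLT immediate/delayed recall as a random walk driven by `y_it` in
#' component z-units. Baseline staging-test scores are drawn so MCI-labelled
#' participants satisfy the actuarial MCI rule (both episodic-memory tests
#' impaired) and preclinical-labelled participants have no impaired score;
#' preclinical baseline ratios are truncated at the positivity cut-point so
#' the generated label is recoverable by [stage_baseline()].
#'
#' @param config a [cohort_config()].
#' @param effects a [true_effects()] / [effect_preset()] object; a preset name
#'   string is accepted. A stratified preset requires a single-group `cells`.
#' @return A long data frame, one row per participant-visit, with fixed column
#'   order: `pid`, `visit` (0-based), `sex`, `group`, `age_baseline`,
#'   `education`, `apoe4`, `biomarker_ratio`, `ravlt_immediate`,
#'   `ravlt_delayed`, `tmt_a`, `tmt_b`, `category_fluency`, `boston_naming`,
#'   `ravlt_recognition`, `biomarker_positive`, `dementia`, and (direct mode
#'   only) `truth_intercept`, `truth_biomarker_change`, `truth_memory_change`.
#'   The config is attached as attribute `"config"`.
#' @export
simulate_cohort <- function(config, effects = effect_preset("full")) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.character(effects)) effects <- effect_preset(effects)
  validate_true_effects(effects)
  cells <- config$cells
  if (effects$stratified) {
    groups_present <- c(any(cells[c("preclinical_female", "preclinical_male")] > 0),
                        any(cells[c("mci_female", "mci_male")] > 0))
    if (all(groups_present)) {
      stop("stratified effects describe a single-group model; use cells with one diagnostic group",
           call. = FALSE)
    }
  }
  set.seed(config$seed)
  n <- sum(cells)
  grp <- rep(c("preclinical", "preclinical", "MCI", "MCI"), cells)
  sex <- rep(c("female", "male", "female", "male"), cells)
  pid <- sprintf("P%05d", seq_len(n))
  age <- clamp(stats::rnorm(n, config$age_mean, config$age_sd), 55, 88)
  edu <- clamp(round(stats::rnorm(n, config$edu_mean, config$edu_sd)), 6, 20)
  apoe <- stats::rbinom(n, 1, config$apoe_prev)
  sex_num <- sex_indicator(sex, config$sex_coding)
  grp_num <- group_indicator(grp, config$group_coding)
  mci <- grp == "MCI"

  b_i <- stats::rnorm(n, 0, sqrt(effects$tau00))
  TT <- config$n_visits

  # baseline biomarker ratio; preclinical AD requires biomarker positivity
  r0 <- numeric(n)
  r0[!mci] <- rtruncnorm1(sum(!mci), config$ratio_baseline_mean,
                          config$ratio_baseline_sd, lower = config$cutpoint)
  r0[mci] <- rtruncnorm1(sum(mci), config$ratio_baseline_mean,
                         config$ratio_baseline_sd, lower = 0)

  zmat <- draw_staging_z(n, mci)
  z_del0 <- zmat[, "ravlt_delayed"]
  z_imm0 <- 0.7 * z_del0 + sqrt(1 - 0.7^2) * stats::rnorm(n)

  # design rows for the change model (covariates centred at config means)
  x_terms <- names(effects$beta)
  xrow <- cbind(
    "(Intercept)" = 1, biomarker_change = 0, sex = sex_num, group = grp_num,
    age_c = age - config$age_mean, edu_c = edu - config$edu_mean, apoe4 = apoe,
    "biomarker_change:sex" = 0, "biomarker_change:group" = 0,
    "sex:group" = sex_num * grp_num, "biomarker_change:sex:group" = 0
  )

  u <- matrix(stats::rnorm(n * (TT - 1), 0, config$innovation_sd_biomarker), n, TT - 1)
  eps <- matrix(stats::rnorm(n * (TT - 1), 0, sqrt(effects$sigma2)), n, TT - 1)
  y <- matrix(NA_real_, n, TT - 1)
  for (t in seq_len(TT - 1)) {
    xt <- xrow
    xt[, "biomarker_change"] <- u[, t]
    xt[, "biomarker_change:sex"] <- u[, t] * sex_num
    xt[, "biomarker_change:group"] <- u[, t] * grp_num
    xt[, "biomarker_change:sex:group"] <- u[, t] * sex_num * grp_num
    y[, t] <- drop(xt[, x_terms, drop = FALSE] %*% effects$beta) + b_i + eps[, t]
  }

  # raw biomarker series (AR(1) with innovations u) and memory random walk
  ratio <- matrix(NA_real_, n, TT); ratio[, 1] <- r0
  z_imm <- matrix(NA_real_, n, TT); z_imm[, 1] <- z_imm0
  z_del <- matrix(NA_real_, n, TT); z_del[, 1] <- z_del0
  phi_m <- config$ar_slope_memory
  for (t in 2:TT) {
    ratio[, t] <- pmax(config$ar_intercept + config$ar_slope * ratio[, t - 1] + u[, t - 1], 0)
    z_imm[, t] <- phi_m * z_imm[, t - 1] + y[, t - 1]
    z_del[, t] <- phi_m * z_del[, t - 1] + y[, t - 1]
  }

  raw_score <- function(test, zval) {
    nt <- .normative_truth[.normative_truth$test == test, ]
    pred <- norm_predict_truth(test, age, sex_num, edu)
    sgn <- if (nt$higher_is_better) 1 else -1
    rng <- score_range(test)
    clamp(round(pred + sgn * zval * nt$residual_sd), rng[1], rng[2])
  }

  long <- data.frame(
    pid = rep(pid, each = TT),
    visit = rep(0:(TT - 1), times = n),
    sex = rep(sex, each = TT),
    group = rep(grp, each = TT),
    age_baseline = rep(age, each = TT),
    education = rep(edu, each = TT),
    apoe4 = rep(apoe, each = TT),
    biomarker_ratio = as.vector(t(ratio)),
    ravlt_immediate = as.vector(t(matrix(raw_score("ravlt_immediate", z_imm), n, TT))),
    ravlt_delayed = as.vector(t(matrix(raw_score("ravlt_delayed", z_del), n, TT))),
    stringsAsFactors = FALSE
  )
  # four non-memory staging tests: baseline value per the drawn z, follow-up
  # visits add small test-retest jitter (unused downstream; staging is
  # baseline-only)
  for (tst in c("tmt_a", "tmt_b", "category_fluency", "boston_naming",
                "ravlt_recognition")) {
    base_val <- raw_score(tst, zmat[, tst])
    nt <- .normative_truth[.normative_truth$test == tst, ]
    vals <- matrix(rep(base_val, each = TT), TT, n)
    if (TT > 1) {
      jit <- matrix(stats::rnorm(n * (TT - 1), 0, 0.3 * nt$residual_sd), TT - 1, n)
      rng <- score_range(tst)
      vals[-1, ] <- clamp(round(vals[-1, ] + jit), rng[1], rng[2])
    }
    long[[tst]] <- as.vector(vals)
  }
  long$biomarker_positive <- rep(r0 >= config$cutpoint, each = TT)
  long$dementia <- FALSE
  long <- long[, c("pid", "visit", "sex", "group", "age_baseline", "education",
                   "apoe4", "biomarker_ratio", "ravlt_immediate", "ravlt_delayed",
                   "tmt_a", "tmt_b", "category_fluency", "boston_naming",
                   "ravlt_recognition", "biomarker_positive", "dementia")]
  if (config$mode == "direct") {
    na_first <- function(m) as.vector(t(cbind(NA_real_, m)))
    long$truth_intercept <- rep(b_i, each = TT)
    long$truth_biomarker_change <- na_first(u)
    long$truth_memory_change <- na_first(y)
  }
  attr(long, "config") <- config
  attr(long, "effects_name") <- effects$name
  long
}

#' Generate a synthetic normative reference sample
#'
#' Draws an unimpaired reference sample whose seven test scores (six staging
#' tests plus RAVLT immediate recall) follow the known linear normative models
#' in [normative_truth()] with Gaussian residuals, so [fit_norms()] can be
#' validated against the generating coefficients.
#'
#' @param n number of reference participants.
#' @param seed integer seed.
#' @param age_mean,age_sd,edu_mean,edu_sd covariate distributions (defaults as
#'   in [cohort_config()]).
#' @param sex_coding indicator coding used when scores are generated.
#' @return A data frame with columns `pid`, `age`, `sex`, `education` and one
#'   column per test (raw score scale, integer-rounded).
#' @export
simulate_reference <- function(n = 2000, seed = 1L, age_mean = 74, age_sd = 6.5,
                               edu_mean = 16, edu_sd = 2.7,
                               sex_coding = c(female = 1, male = 0)) {
  stopifnot_positive(n, "n")
  for (nm in c("age_sd", "edu_sd")) stopifnot_positive(get(nm), nm)
  set.seed(as.integer(seed))
  age <- clamp(stats::rnorm(n, age_mean, age_sd), 55, 90)
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  edu <- clamp(round(stats::rnorm(n, edu_mean, edu_sd)), 6, 20)
  sex_num <- sex_indicator(sex, sex_coding)
  out <- data.frame(pid = sprintf("R%05d", seq_len(n)), age = age, sex = sex,
                    education = edu, stringsAsFactors = FALSE)
  for (tst in .normative_truth$test) {
    nt <- .normative_truth[.normative_truth$test == tst, ]
    out[[tst]] <- round(norm_predict_truth(tst, age, sex_num, edu) +
                          stats::rnorm(n, 0, nt$residual_sd))
  }
  out
}

#' Read and write cohort CSV files
#'
#' The long-format CSV is the single interchange format: one row per
#' participant-visit, columns in the order documented in [simulate_cohort()].
#' The generating seed (when known) is recorded as a `# seed:` comment line.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort()` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) writeLines(sprintf("# seed: %d", cfg$seed), con)
  utils::write.csv(cohort, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_cohort(df)
  df
}

#' Validate the long-format cohort schema
#'
#' Checks required columns, visit indexing (0-based, strictly increasing and
#' gap-free within participant) and score ranges.
#'
#' @param cohort long-format cohort data frame.
#' @return The cohort, invisibly; errors name the offending column or pid.
#' @export
validate_cohort <- function(cohort) {
  req <- c("pid", "visit", "sex", "group", "age_baseline", "education", "apoe4",
           "biomarker_ratio", "ravlt_immediate", "ravlt_delayed", "tmt_a",
           "tmt_b", "category_fluency", "boston_naming", "ravlt_recognition",
           "biomarker_positive", "dementia")
  require_columns(cohort, req, "cohort")
  by_pid <- split(cohort$visit, cohort$pid)
  gapfree <- function(v) {
    !anyDuplicated(v) && all(sort(v) == seq(min(v), by = 1, length.out = length(v)))
  }
  bad <- names(by_pid)[!vapply(by_pid, gapfree, logical(1))]
  if (length(bad)) {
    stop("visit indices must be strictly increasing and gap-free; offending pid(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(cohort$biomarker_ratio < 0, na.rm = TRUE)) {
    stop("biomarker_ratio must be non-negative", call. = FALSE)
  }
  rng_ok <- function(x, lo, hi) all(x >= lo & x <= hi, na.rm = TRUE)
  if (!rng_ok(cohort$ravlt_immediate, 0, 75)) stop("ravlt_immediate outside 0-75", call. = FALSE)
  if (!rng_ok(cohort$ravlt_delayed, 0, 15)) stop("ravlt_delayed outside 0-15", call. = FALSE)
  invisible(cohort)
}
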