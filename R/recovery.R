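# Monte-Carlo parameter recovery, CI coverage and type-I calibration for the
# random-intercept change-on-change estimator, run on direct-mode synthetic
# cohorts where the generative truth is known exactly.

# analysis frame assembled from a direct-mode cohort's hidden truth columns:
# the estimator sees the change variables the generative model produced,
# with covariates centred at the sample mean as the analysis convention.
truth_change_table <- function(cohort, sex_coding = c(female = 1, male = 0),
                               group_coding = c(MCI = 1, preclinical = 0)) {
  require_columns(cohort, c("truth_biomarker_change", "truth_memory_change"),
                  "direct-mode cohort")
  d <- cohort[cohort$visit > 0, , drop = FALSE]
  base <- cohort[cohort$visit == 0, c("pid", "age_baseline", "education")]
  data.frame(
    pid = d$pid, visit = d$visit,
    biomarker_change = d$truth_biomarker_change,
    memory_change = d$truth_memory_change,
    sex = sex_indicator(d$sex, sex_coding),
    group = group_indicator(d$group, group_coding),
    age_c = d$age_baseline - mean(base$age_baseline),
    edu_c = d$education - mean(base$education),
    apoe4 = d$apoe4,
    stringsAsFactors = FALSE
  )
}

default_cells <- function(preset) {
  switch(preset,
    full = ,
    null = c(preclinical_female = 78, preclinical_male = 73,
             mci_female = 104, mci_male = 146),
    preclinical = c(preclinical_female = 69, preclinical_male = 69,
                    mci_female = 0, mci_male = 0),
    mci = c(preclinical_female = 0, preclinical_male = 0,
            mci_female = 113, mci_male = 152)
  )
}

#' Monte-Carlo recovery study for the change-on-change estimator
#'
#' Repeatedly generates direct-mode synthetic cohorts under a true-effect
#' preset, fits the corresponding random-intercept model (full three-way
#' model for the two-group presets, stratified two-way model for the
#' single-group presets) to the generative change variables, and summarizes
#' per-term estimates: replicate mean, Monte-Carlo standard error of that
#' mean, bias against truth, empirical 95% Wald CI coverage of the truth,
#' and the Wald rejection rate at alpha = 0.05.
#'
#' @param preset preset name or `"true_effects"` object.
#' @param cells per-cell sample sizes; defaults match the preset (pooled
#'   cohort 78/73/104/146; preclinical stratum 69/69; MCI stratum 113/152).
#' @param n_visits visits per participant.
#' @param replicates number of Monte-Carlo replicates.
#' @param seed integer seed; replicate r uses seed + r - 1.
#' @param reml estimation method passed to [fit_lmm()].
#' @return An object of class `"recovery_study"`: list with `estimates`
#'   (replicates x terms matrix), `se` (matrix of per-replicate Wald SEs),
#'   `truth`, and `summary` (data frame: `term`, `truth`, `mean`, `mc_se`,
#'   `bias`, `coverage`, `reject_rate`), plus `n_participants` and
#'   `replicates`.
#' @export
recovery_study <- function(preset = "full", cells = NULL, n_visits = 5,
                           replicates = 200, seed = 1L, reml = TRUE) {
  eff <- if (is.character(preset)) effect_preset(preset) else preset
  validate_true_effects(eff)
  if (is.null(cells)) {
    if (!eff$name %in% c("full", "null", "preclinical", "mci")) {
      stop("cells must be given for a custom true-effects object", call. = FALSE)
    }
    cells <- default_cells(eff$name)
  }
  terms <- names(eff$beta)
  R <- as.integer(replicates)
  est <- se <- matrix(NA_real_, R, length(terms), dimnames = list(NULL, terms))
  conv <- logical(R)
  for (r in seq_len(R)) {
    cfg <- cohort_config(cells = cells, n_visits = n_visits, mode = "direct",
                         seed = as.integer(seed) + r - 1L)
    cohort <- simulate_cohort(cfg, eff)
    tab <- truth_change_table(cohort)
    fit <- fit_lmm(tab, stratified = eff$stratified, reml = reml)
    cf <- fit$coefficients
    est[r, cf$term] <- cf$estimate
    se[r, cf$term] <- cf$se
    conv[r] <- fit$converged
  }
  truth <- eff$beta[terms]
  covered <- abs(est - matrix(truth, R, length(terms), byrow = TRUE)) <= 1.96 * se
  reject <- abs(est / se) > stats::qnorm(0.975)
  summ <- data.frame(
    term = terms,
    truth = unname(truth),
    mean = colMeans(est),
    mc_se = apply(est, 2, stats::sd) / sqrt(R),
    bias = colMeans(est) - unname(truth),
    coverage = colMeans(covered),
    reject_rate = colMeans(reject),
    stringsAsFactors = FALSE
  )
  rownames(summ) <- NULL
  structure(list(
    estimates = est, se = se, truth = truth, summary = summ,
    preset = eff$name, replicates = R, converged = conv,
    n_participants = sum(cells), n_visits = n_visits
  ), class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, digits = 3, ...) {
  cat(sprintf("Recovery study: preset '%s', %d replicates, %d participants, %d visits\n",
              x$preset, x$replicates, x$n_participants, x$n_visits))
  s <- x$summary
  s[, c("truth", "mean", "mc_se", "bias")] <-
    round(s[, c("truth", "mean", "mc_se", "bias")], digits)
  s$coverage <- round(s$coverage, 3)
  s$reject_rate <- round(s$reject_rate, 3)
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}
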