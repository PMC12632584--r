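# Built-in generative truth: fixed effects and variance components for the
# random-intercept change-on-change models, on the scale of the analysis
# variables (memory change in composite z-units, biomarker change in raw
# pTau181/Abeta42 ratio units, hence the large biomarker coefficients).

.model_terms_full <- c(
  "(Intercept)", "biomarker_change", "sex", "group", "age_c", "edu_c",
  "apoe4", "biomarker_change:sex", "biomarker_change:group", "sex:group",
  "biomarker_change:sex:group"
)

.model_terms_stratified <- c(
  "(Intercept)", "biomarker_change", "sex", "age_c", "edu_c", "apoe4",
  "biomarker_change:sex"
)

.interaction_terms <- c(
  "biomarker_change:sex", "biomarker_change:group", "sex:group",
  "biomarker_change:sex:group"
)

#' Built-in true-effect presets for the synthetic cohort generator
#'
#' Returns a set of fixed-effect coefficients and variance components used as
#' generative truth by [simulate_cohort()]. The presets encode effect sizes at
#' the scale reported in longitudinal ADNI-style cohorts of the early
#' Alzheimer's continuum, with sex coded female = 1 and diagnostic group coded
#' MCI = 1:
#'
#' * `"full"` — the pooled two-group model with the full interaction set
#'   (biomarker change x sex, x group, sex x group, and the three-way term
#'   `biomarker_change:sex:group` = -17.47), between-participant intercept
#'   variance `tau00 = 0.12` and residual variance `sigma2 = 0.56`.
#' * `"preclinical"` — the preclinical-AD stratum model (no group terms);
#'   biomarker x sex interaction -3.73, `tau00 = 0.05`, `sigma2 = 0.31`.
#' * `"mci"` — the MCI stratum model; biomarker main effect -23.98,
#'   sex -0.10, biomarker x sex interaction 10.17, `tau00 = 0.02`,
#'   `sigma2 = 0.10`.
#' * `"null"` — the `"full"` design with every interaction coefficient set to
#'   zero (used for type-I-error calibration).
#'
#' Each preset is a self-contained reference condition. The stratum effects
#' implied by the pooled `"full"` preset (e.g. the MCI biomarker slope
#' `-19.97 + 22.91`) deliberately differ from the `"mci"`/`"preclinical"`
#' presets, which encode the stratified models' own reported scale; a
#' stratified fit on a `"full"`-preset cohort recovers the former, not the
#' latter.
#'
#' @param name one of `"full"`, `"preclinical"`, `"mci"`, `"null"`.
#' @return An object of class `"true_effects"`: a list with elements `beta`
#'   (named numeric vector of fixed effects, names matching the model terms),
#'   `tau00` (between-participant intercept variance), `sigma2` (residual
#'   variance), `stratified` (logical; `TRUE` when the preset describes a
#'   single-group stratum model) and `name`.
#' @seealso [simulate_cohort()], [fit_lmm()], [recovery_study()]
#' @examples
#' effect_preset("mci")$beta[["biomarker_change:sex"]]
#' @export
effect_preset <- function(name) {
  valid <- c("full", "preclinical", "mci", "null")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop("unknown preset ", deparse(substitute(name)), ": '", paste(name, collapse = ","),
         "'; valid presets are: ", paste(sQuote(valid), collapse = ", "), call. = FALSE)
  }
  full_beta <- c(
    "(Intercept)"                = 0.75,
    "biomarker_change"           = -19.97,
    "sex"                        = -0.32,
    "group"                      = -0.84,
    "age_c"                      = -0.01,
    "edu_c"                      = 0.01,
    "apoe4"                      = -0.11,
    "biomarker_change:sex"       = 8.05,
    "biomarker_change:group"     = 22.91,
    "sex:group"                  = 1.05,
    "biomarker_change:sex:group" = -17.47
  )
  eff <- switch(name,
    full = list(beta = full_beta, tau00 = 0.12, sigma2 = 0.56, stratified = FALSE),
    null = {
      b <- full_beta
      b[.interaction_terms] <- 0
      list(beta = b, tau00 = 0.12, sigma2 = 0.56, stratified = FALSE)
    },
    preclinical = list(
      beta = c(
        "(Intercept)"          = 0.15,
        "biomarker_change"     = -9.10,
        "sex"                  = -0.10,
        "age_c"                = -0.01,
        "edu_c"                = 0.02,
        "apoe4"                = -0.15,
        "biomarker_change:sex" = -3.73
      ),
      tau00 = 0.05, sigma2 = 0.31, stratified = TRUE
    ),
    mci = list(
      beta = c(
        "(Intercept)"          = 0.07,
        "biomarker_change"     = -23.98,
        "sex"                  = -0.10,
        "age_c"                = 0.00,
        "edu_c"                = -0.01,
        "apoe4"                = 0.04,
        "biomarker_change:sex" = 10.17
      ),
      tau00 = 0.02, sigma2 = 0.10, stratified = TRUE
    )
  )
  eff$name <- name
  class(eff) <- "true_effects"
  validate_true_effects(eff)
  eff
}

#' Construct or validate a set of generative true effects
#'
#' @param beta named numeric vector of fixed effects; names must match the
#'   model terms of [fit_lmm()] (full or stratified set).
#' @param tau00 between-participant intercept variance (>= 0).
#' @param sigma2 residual variance (> 0).
#' @param stratified logical; `TRUE` for a single-group stratum model.
#' @return A `"true_effects"` object.
#' @export
true_effects <- function(beta, tau00, sigma2, stratified = FALSE) {
  eff <- structure(
    list(beta = beta, tau00 = tau00, sigma2 = sigma2,
         stratified = isTRUE(stratified), name = "custom"),
    class = "true_effects"
  )
  validate_true_effects(eff)
  eff
}

validate_true_effects <- function(eff) {
  expected <- if (isTRUE(eff$stratified)) .model_terms_stratified else .model_terms_full
  if (!is.numeric(eff$beta) || is.null(names(eff$beta)) ||
      !setequal(names(eff$beta), expected)) {
    stop("true effects must be a named numeric vector with terms exactly {",
         paste(expected, collapse = ", "), "}", call. = FALSE)
  }
  if (!is.numeric(eff$tau00) || length(eff$tau00) != 1L || eff$tau00 < 0) {
    stop("tau00 must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(eff$sigma2) || length(eff$sigma2) != 1L || eff$sigma2 <= 0) {
    stop("sigma2 must be a single positive number", call. = FALSE)
  }
  invisible(eff)
}

#' @export
print.true_effects <- function(x, ...) {
  cat("True effects preset:", x$name,
      if (x$stratified) "(stratified model)\n" else "(full two-group model)\n")
  print(round(x$beta, 4))
  cat(sprintf("tau00 = %.3f, sigma2 = %.3f, ICC = %.3f\n",
              x$tau00, x$sigma2, icc(x$tau00, x$sigma2)))
  invisible(x)
}

# Six staging tests, their cognitive domains, and the generating normative
# model used by simulate_reference()/simulate_cohort(). Coefficients are on
# the raw score scale with covariates (age in years, sex indicator, education
# in years) uncentred. TMT scores are times in seconds (lower is better).
.staging_domains <- list(
  speed_exec = c("tmt_a", "tmt_b"),
  language   = c("category_fluency", "boston_naming"),
  memory     = c("ravlt_delayed", "ravlt_recognition")
)

.staging_tests <- unlist(.staging_domains, use.names = FALSE)

#' Tests and domains used for actuarial staging
#'
#' @return `staging_tests()` returns the six test names; `staging_domains()`
#'   the list of three cognitive domains of two tests each (psychomotor
#'   speed / executive function, language, episodic memory).
#' @export
staging_tests <- function() .staging_tests

#' @rdname staging_tests
#' @export
staging_domains <- function() .staging_domains

.normative_truth <- data.frame(
  test = c("tmt_a", "tmt_b", "category_fluency", "boston_naming",
           "ravlt_delayed", "ravlt_recognition", "ravlt_immediate"),
  intercept   = c(8.0, 20.0, 26.0, 26.0, 12.0, 14.0, 55.0),
  coef_age    = c(0.45, 1.10, -0.15, -0.04, -0.10, -0.04, -0.30),
  coef_sex    = c(-1.0, -2.0, 1.0, -0.5, 1.7, 0.7, 6.0),
  coef_edu    = c(-0.50, -1.50, 0.30, 0.20, 0.15, 0.05, 0.50),
  residual_sd = c(8.0, 20.0, 4.5, 2.5, 2.8, 1.8, 10.0),
  higher_is_better = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Generating normative models behind the synthetic reference sample
#'
#' The linear models (raw score ~ age + sex + education, Gaussian residuals)
#' from which [simulate_reference()] draws test scores. Exposed so that
#' coefficient recovery by [fit_norms()] can be checked against truth. The
#' extra `ravlt_immediate` row drives the verbal-memory composite and is not a
#' staging test.
#'
#' @return A data frame with one row per test: `test`, `intercept`,
#'   `coef_age`, `coef_sex`, `coef_edu`, `residual_sd`, `higher_is_better`.
#' @export
normative_truth <- function() .normative_truth
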