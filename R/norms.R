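# Regression-based normative scoring: per-test OLS of raw score on age, sex
# and education in a reference sample, and conversion of raw scores into
# demographically corrected z-scores with impairment flags.

.norms_columns <- c("test", "intercept", "coef_age", "coef_sex", "coef_edu",
                    "residual_sd", "higher_is_better")

#' Fit per-test normative regressions on a reference sample
#'
#' For each test, fits `score ~ age + sex + education` by ordinary least
#' squares on the reference sample and stores the coefficients together with
#' the degrees-of-freedom-corrected residual standard deviation. Sex enters as
#' a binary indicator with the same coding as the analysis models.
#'
#' @param reference data frame with columns `age`, `sex`, `education` and one
#'   column per test in `tests`.
#' @param tests character vector of test columns to fit; defaults to the six
#'   staging tests plus `ravlt_immediate`.
#' @param higher_is_better named logical vector (per test); defaults follow
#'   the test conventions (timed Trail-Making tests are lower-is-better).
#' @param sex_coding indicator coding, default female = 1.
#' @return An object of class `"normative_models"`: a data frame with one row
#'   per test and columns `r .norms_columns`.
#' @export
fit_norms <- function(reference, tests = normative_truth()$test,
                      higher_is_better = NULL,
                      sex_coding = c(female = 1, male = 0)) {
  require_columns(reference, c("age", "sex", "education", tests), "reference sample")
  if (is.null(higher_is_better)) {
    hib <- stats::setNames(.normative_truth$higher_is_better, .normative_truth$test)
    extra <- setdiff(tests, names(hib))
    if (length(extra)) hib[extra] <- TRUE
    higher_is_better <- hib[tests]
  }
  sex_num <- sex_indicator(reference$sex, sex_coding)
  covars <- list(age = reference$age, sex = sex_num, edu = reference$education)
  const <- names(covars)[vapply(covars, function(x) stats::var(x) == 0, logical(1))]
  rows <- lapply(tests, function(tst) {
    y <- reference[[tst]]
    if (sum(!is.na(y)) < 10) {
      stop("test '", tst, "': fewer than 10 reference rows", call. = FALSE)
    }
    if (length(const)) {
      stop("test '", tst, "': constant covariate(s) ", paste(const, collapse = ", "),
           " make the normative regression unidentifiable", call. = FALSE)
    }
    fit <- stats::lm(y ~ covars$age + covars$sex + covars$edu)
    if (any(is.na(stats::coef(fit)))) {
      stop("test '", tst, "': collinear covariates in the normative regression",
           call. = FALSE)
    }
    rsd <- summary(fit)$sigma
    if (!is.finite(rsd) || rsd <= 1e-8) {
      stop("test '", tst, "': zero residual variance in the reference sample",
           call. = FALSE)
    }
    cf <- stats::coef(fit)
    data.frame(test = tst, intercept = cf[[1]], coef_age = cf[[2]],
               coef_sex = cf[[3]], coef_edu = cf[[4]], residual_sd = rsd,
               higher_is_better = unname(higher_is_better[[tst]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sex_coding") <- sex_coding
  class(out) <- c("normative_models", "data.frame")
  out
}

#' Demographically corrected z-score for a raw test score
#'
#' Computes `z = s * (raw - predicted) / residual_sd` where `predicted` is the
#' normative regression prediction for the participant's age, sex and
#' education, and `s` is +1 for higher-is-better tests and -1 for timed tests
#' (TMT-A/B), so a lower z always means worse performance.
#'
#' @param raw raw score(s).
#' @param age,sex,education covariates (sex as `"female"`/`"male"` labels or
#'   an already-coded 0/1 indicator).
#' @param model a single-row subset of a `"normative_models"` object (or a
#'   list with the same fields).
#' @param sex_coding indicator coding used when `sex` is given as labels.
#' @return Numeric z-score(s).
#' @export
z_score <- function(raw, age, sex, education, model,
                    sex_coding = c(female = 1, male = 0)) {
  if (is.data.frame(model)) {
    stopifnot(nrow(model) == 1L)
    model <- as.list(model)
  }
  if (any(is.na(raw)) || any(is.na(age)) || any(is.na(sex)) || any(is.na(education))) {
    stop("z_score: missing raw score or covariate", call. = FALSE)
  }
  sex_num <- if (is.character(sex) || is.factor(sex)) {
    sex_indicator(as.character(sex), sex_coding)
  } else as.numeric(sex)
  pred <- model$intercept + model$coef_age * age + model$coef_sex * sex_num +
    model$coef_edu * education
  sgn <- if (isTRUE(model$higher_is_better)) 1 else -1
  sgn * (raw - pred) / model$residual_sd
}

#' Impairment flag from a corrected z-score
#'
#' A score is impaired when it lies strictly more than 1 SD below the
#' demographically corrected normative mean, i.e. `z < -1`; the boundary
#' `z = -1` counts as unimpaired.
#'
#' @param z numeric z-score(s); must be finite.
#' @return Logical vector.
#' @export
flag_impaired <- function(z) {
  if (any(!is.finite(z))) stop("flag_impaired: non-finite z-score", call. = FALSE)
  z < -1
}

#' Serialize normative models to/from CSV
#'
#' @param norms a `"normative_models"` object.
#' @param path file path.
#' @return `read_norms()` returns the `"normative_models"` object.
#' @export
write_norms <- function(norms, path) {
  stopifnot(inherits(norms, "normative_models"))
  utils::write.csv(as.data.frame(norms)[, .norms_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, .norms_columns, "norms file")
  if (any(df$residual_sd <= 0)) stop("norms file has non-positive residual_sd", call. = FALSE)
  class(df) <- c("normative_models", "data.frame")
  df
}

#' @export
print.normative_models <- function(x, ...) {
  cat("Normative regression models (", nrow(x), " tests)\n", sep = "")
  print.data.frame(cbind(x[, "test", drop = FALSE],
                         round(x[, c("intercept", "coef_age", "coef_sex",
                                     "coef_edu", "residual_sd")], 3),
                         x[, "higher_is_better", drop = FALSE]),
                   row.names = FALSE)
  invisible(x)
}
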