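# Verbal memory composite and lagged-residual change scores.

#' Baseline standardization constants for the memory composite
#'
#' Means and SDs of RAVLT immediate and delayed recall in the baseline visit
#' of the analytic sample; the same constants are applied at every visit so
#' longitudinal change stays in baseline SD units.
#'
#' @param cohort long-format cohort.
#' @param baseline_visit baseline visit index.
#' @return A list with `imm_mean`, `imm_sd`, `del_mean`, `del_sd`.
#' @export
baseline_standardization <- function(cohort, baseline_visit = 0L) {
  base <- cohort[cohort$visit == baseline_visit, ]
  out <- list(
    imm_mean = mean(base$ravlt_immediate, na.rm = TRUE),
    imm_sd = stats::sd(base$ravlt_immediate, na.rm = TRUE),
    del_mean = mean(base$ravlt_delayed, na.rm = TRUE),
    del_sd = stats::sd(base$ravlt_delayed, na.rm = TRUE)
  )
  if (!is.finite(out$imm_sd) || out$imm_sd <= 0 ||
      !is.finite(out$del_sd) || out$del_sd <= 0) {
    stop("zero or undefined SD in the baseline standardization sample", call. = FALSE)
  }
  out
}

#' Verbal memory composite score
#'
#' z-scores RAVLT immediate recall (0-75) and delayed recall (0-15) against
#' the supplied standardization constants and returns the arithmetic mean of
#' the two z-scores. If either component is missing the composite is missing
#' (no single-component fallback).
#'
#' @param immediate,delayed raw scores (vectors of equal length).
#' @param standardization list with `imm_mean`, `imm_sd`, `del_mean`,
#'   `del_sd` (see [baseline_standardization()]).
#' @return Numeric composite in z-units.
#' @export
memory_composite <- function(immediate, delayed, standardization) {
  s <- standardization
  req <- c("imm_mean", "imm_sd", "del_mean", "del_sd")
  if (!all(req %in% names(s))) {
    stop("standardization must supply ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (s$imm_sd <= 0 || s$del_sd <= 0) {
    stop("standardization SDs must be positive", call. = FALSE)
  }
  if (any(immediate < 0 | immediate > 75, na.rm = TRUE)) {
    stop("immediate recall outside admissible range 0-75", call. = FALSE)
  }
  if (any(delayed < 0 | delayed > 15, na.rm = TRUE)) {
    stop("delayed recall outside admissible range 0-15", call. = FALSE)
  }
  zi <- (immediate - s$imm_mean) / s$imm_sd
  zd <- (delayed - s$del_mean) / s$del_sd
  (zi + zd) / 2
}

#' Lagged-residual change scores
#'
#' Regresses a variable's value at visit t on its value at visit t-1 in one
#' ordinary least-squares fit pooled over all adjacent person-visit pairs, and
#' returns the residuals — deviations from the value expected given the prior
#' level — as the change score assigned to visit t. Pairs separated by a
#' missing visit or with a missing endpoint are dropped (a lag of one time
#' point is literal) and counted in the `dropped` attribute. Residualizing on
#' the prior level removes the autocorrelation a raw difference would carry.
#'
#' @param data long-format data frame.
#' @param variable name of the value column.
#' @param pid,visit names of the participant-id and visit-index columns.
#' @return Data frame `pid`, `visit`, `residual` (one row per usable pair),
#'   with attributes `intercept`, `slope`, `n_pairs`, `dropped`.
#' @export
lagged_residuals <- function(data, variable, pid = "pid", visit = "visit") {
  require_columns(data, c(pid, visit, variable), "series table")
  d <- data[order(data[[pid]], data[[visit]]), c(pid, visit, variable)]
  names(d) <- c("pid", "visit", "value")
  prev <- d
  prev$visit <- prev$visit + 1L
  names(prev)[3] <- "value_lag"
  pairs <- merge(d, prev, by = c("pid", "visit"))
  usable <- stats::complete.cases(pairs[, c("value", "value_lag")])
  dropped <- nrow(pairs) - sum(usable)
  pairs <- pairs[usable, , drop = FALSE]
  if (nrow(pairs) < 3) {
    stop("need at least 3 usable adjacent-visit pairs for '", variable, "'",
         call. = FALSE)
  }
  if (stats::var(pairs$value_lag) == 0) {
    stop("lagged predictor for '", variable, "' is constant; slope undefined",
         call. = FALSE)
  }
  fit <- stats::lm(value ~ value_lag, data = pairs)
  out <- data.frame(pid = pairs$pid, visit = pairs$visit,
                    residual = unname(stats::resid(fit)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pid, out$visit), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "intercept") <- unname(stats::coef(fit)[1])
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  attr(out, "n_pairs") <- nrow(pairs)
  attr(out, "dropped") <- dropped
  out
}

#' Build the change-score table for modelling
#'
#' Computes the memory composite per visit, then lagged residuals for the
#' biomarker ratio and the composite, and joins them with the baseline
#' covariates the models adjust for (centred age and education, APOE-e4) and
#' the sex/group indicators.
#'
#' @param cohort long-format cohort restricted to the analytic sample.
#' @param labels optional named character vector of per-pid stage labels
#'   (`"preclinical_AD"` / `"MCI"`); defaults to the cohort's `group` column.
#' @param standardization composite standardization constants; defaults to
#'   [baseline_standardization()] of `cohort`.
#' @param sex_coding,group_coding indicator codings.
#' @return Data frame with one row per usable (t-1, t) pair: `pid`, `visit`,
#'   `biomarker_change`, `memory_change`, `sex`, `group`, `age_c`, `edu_c`,
#'   `apoe4`, plus label columns `sex_label`, `group_label`,
#'   `biomarker_positive`. Attributes carry the lag-regression coefficients.
#' @export
build_change_table <- function(cohort, labels = NULL, standardization = NULL,
                               sex_coding = c(female = 1, male = 0),
                               group_coding = c(MCI = 1, preclinical = 0)) {
  validate_cohort(cohort)
  if (is.null(standardization)) standardization <- baseline_standardization(cohort)
  cohort$memory_composite <- memory_composite(cohort$ravlt_immediate,
                                              cohort$ravlt_delayed, standardization)
  bio <- lagged_residuals(cohort, "biomarker_ratio")
  mem <- lagged_residuals(cohort, "memory_composite")
  names(bio)[3] <- "biomarker_change"
  names(mem)[3] <- "memory_change"
  tab <- merge(bio, mem, by = c("pid", "visit"))
  base <- cohort[cohort$visit == 0, c("pid", "sex", "group", "age_baseline",
                                      "education", "apoe4", "biomarker_positive")]
  if (!is.null(labels)) {
    base$group <- ifelse(unname(labels[base$pid]) == "MCI", "MCI", "preclinical")
  }
  tab <- merge(tab, base, by = "pid")
  tab$sex_label <- tab$sex
  tab$group_label <- tab$group
  tab$sex <- sex_indicator(tab$sex_label, sex_coding)
  tab$group <- group_indicator(tab$group_label, group_coding)
  tab$age_c <- tab$age_baseline - mean(base$age_baseline)
  tab$edu_c <- tab$education - mean(base$education)
  tab <- tab[order(tab$pid, tab$visit), ]
  rownames(tab) <- NULL
  attr(tab, "lag_biomarker") <- attributes(bio)[c("intercept", "slope", "n_pairs", "dropped")]
  attr(tab, "lag_memory") <- attributes(mem)[c("intercept", "slope", "n_pairs", "dropped")]
  attr(tab, "standardization") <- standardization
  tab
}
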