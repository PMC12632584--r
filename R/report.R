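# Baseline sex comparisons and the report bundle.

welch_or_pooled <- function(x, by_female, pooled = FALSE) {
  a <- x[by_female]; b <- x[!by_female]
  if (stats::sd(c(a, b), na.rm = TRUE) == 0 ||
      (stats::sd(a, na.rm = TRUE) == 0 && stats::sd(b, na.rm = TRUE) == 0)) {
    # degenerate comparison: no variability within either sex
    same <- isTRUE(all.equal(mean(a, na.rm = TRUE), mean(b, na.rm = TRUE)))
    return(list(statistic = if (same) 0 else Inf, p.value = if (same) 1 else 0))
  }
  stats::t.test(a, b, var.equal = pooled)
}

chisq_row <- function(tab) {
  if (any(tab == 0)) {
    warning("zero cell in a sex-by-category table; applying continuity correction")
    suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
}

#' Baseline sample characteristics compared by sex
#'
#' Builds the table of baseline comparisons between females and males:
#' Welch t-tests (two-sided) for continuous variables and chi-square tests
#' for categorical ones. Covers age, education, APOE-e4 carrier status,
#' diagnostic group, follow-up duration, baseline biomarker ratio, baseline
#' memory composite, and per-participant mean lagged-residual change scores.
#'
#' @param cohort long-format analytic cohort.
#' @param labels optional named per-pid stage labels; defaults to the `group`
#'   column.
#' @param standardization composite standardization; defaults to the cohort's
#'   baseline sample.
#' @param pooled_variance use the pooled-variance t-test instead of Welch.
#' @return An object of class `"baseline_comparison"`: a data frame with one
#'   row per variable: `variable`, `female` and `male` summaries
#'   (`mean (SD)` or `N (%)`), `statistic`, `p`, `test`
#'   (`"welch_t"`/`"pooled_t"`/`"chi_square"`), `n_female`, `n_male`.
#' @export
baseline_table <- function(cohort, labels = NULL, standardization = NULL,
                           pooled_variance = FALSE) {
  validate_cohort(cohort)
  if (is.null(standardization)) standardization <- baseline_standardization(cohort)
  base <- cohort[cohort$visit == 0, , drop = FALSE]
  if (any(is.na(base$sex))) stop("baseline sex must be non-missing", call. = FALSE)
  if (!is.null(labels)) {
    base$group <- ifelse(unname(labels[base$pid]) == "MCI", "MCI", "preclinical")
  }
  base$composite <- memory_composite(base$ravlt_immediate, base$ravlt_delayed,
                                     standardization)
  followup <- tapply(cohort$visit, cohort$pid, function(v) max(v) - min(v))
  base$followup <- as.numeric(followup[base$pid])
  cohort$memory_composite <- memory_composite(cohort$ravlt_immediate,
                                              cohort$ravlt_delayed, standardization)
  add_mean_change <- function(var, name) {
    res <- lagged_residuals(cohort, var)
    m <- tapply(res$residual, res$pid, mean)
    base[[name]] <<- as.numeric(m[base$pid])
  }
  add_mean_change("biomarker_ratio", "biomarker_change")
  add_mean_change("memory_composite", "memory_change")

  f <- base$sex == "female"
  ttest_name <- if (pooled_variance) "pooled_t" else "welch_t"
  msd <- function(x, sel) sprintf("%.2f (%.2f)", mean(x[sel], na.rm = TRUE),
                                  stats::sd(x[sel], na.rm = TRUE))
  rows <- list()
  cont <- c(age = "age_baseline", education = "education",
            followup_years = "followup", baseline_biomarker_ratio = "biomarker_ratio",
            baseline_memory_composite = "composite",
            biomarker_change_score = "biomarker_change",
            memory_change_score = "memory_change")
  for (nm in names(cont)) {
    x <- base[[cont[[nm]]]]
    tt <- welch_or_pooled(x, f, pooled_variance)
    rows[[nm]] <- data.frame(
      variable = nm, female = msd(x, f), male = msd(x, !f),
      statistic = unname(tt$statistic), p = tt$p.value, test = ttest_name,
      stringsAsFactors = FALSE
    )
  }
  npct <- function(x, sel) sprintf("%d (%.1f%%)", sum(x[sel]), 100 * mean(x[sel]))
  cat_vars <- list(apoe4_carrier = as.logical(base$apoe4),
                   mci_group = base$group == "MCI")
  for (nm in names(cat_vars)) {
    x <- cat_vars[[nm]]
    tab <- table(factor(f, c(TRUE, FALSE)), factor(x, c(TRUE, FALSE)))
    ct <- chisq_row(tab)
    rows[[nm]] <- data.frame(
      variable = nm, female = npct(x, f), male = npct(x, !f),
      statistic = unname(ct$statistic), p = ct$p.value, test = "chi_square",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$n_female <- sum(f)
  out$n_male <- sum(!f)
  class(out) <- c("baseline_comparison", "data.frame")
  out
}

#' @export
print.baseline_comparison <- function(x, ...) {
  cat(sprintf("Baseline characteristics by sex (%d female, %d male)\n",
              x$n_female[1], x$n_male[1]))
  y <- as.data.frame(x)
  y$statistic <- round(y$statistic, 2)
  y$p <- format.pval(y$p, digits = 2, eps = 1e-3)
  print.data.frame(y[, c("variable", "female", "male", "statistic", "p", "test")],
                   row.names = FALSE)
  invisible(x)
}

#' Write the analysis report bundle
#'
#' Writes a deterministic report: `baseline.csv`, one CSV per model
#' (`model_full.csv`, `model_preclinical.csv`, `model_mci.csv`,
#' `model_sensitivity.csv`, each mirroring the published-table layout of
#' term / estimate / CI / p plus the variance-component block), a
#' human-readable `summary.txt`, and `run_metadata.json` embedding the seed
#' (when known), a hash of the run configuration and software versions.
#' Models that were not run are marked as such. Re-running the same analysis
#' produces byte-identical report bodies.
#'
#' @param fit a `"memdecline"` object.
#' @param dir output directory (created if needed).
#' @param seed the seed used to produce the input cohort, if any.
#' @return The directory path, invisibly.
#' @export
write_report <- function(fit, dir, seed = NULL) {
  stopifnot(inherits(fit, "memdecline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(fit$baseline), file.path(dir, "baseline.csv"),
                   row.names = FALSE)
  for (nm in names(fit$fits)) {
    utils::write.csv(lmm_as_table(fit$fits[[nm]]),
                     file.path(dir, paste0("model_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(fit$change[, c("pid", "visit", "biomarker_change", "memory_change")],
                   file.path(dir, "change_scores.csv"), row.names = FALSE)
  cfg_json <- jsonlite::toJSON(fit$config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  meta <- list(
    seed = seed, config = fit$config, config_hash = cfg_hash,
    n = fit$n,
    lag_regressions = list(biomarker = attr(fit$change, "lag_biomarker"),
                           memory = attr(fit$change, "lag_memory")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("memdecline")),
    models_run = names(fit$fits)[!vapply(fit$fits, is.null, logical(1))]
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(dir, "run_metadata.json"))
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con)
  on.exit({ sink(); close(con) })
  print(summary(fit))
  for (nm in names(fit$fits)) {
    cat("\n==", nm, "model ==\n")
    if (is.null(fit$fits[[nm]])) cat("not run\n") else print(fit$fits[[nm]])
  }
  invisible(dir)
}
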