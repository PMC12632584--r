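# End-to-end analysis: staging -> composite -> change scores -> four
# random-intercept models, wrapped in a classed model object.

#' Sex- and stage-stratified biomarker-change / memory-decline analysis
#'
#' Runs the full analysis on a long-format cohort: (1) actuarial baseline
#' staging against normative regressions fit on a separate reference sample,
#' (2) exclusion of dementia cases and biomarker-negative cognitively normal
#' participants, (3) the verbal memory composite and lagged-residual change
#' scores for the composite and the CSF pTau181/Abeta42 ratio, and (4) four
#' random-intercept models: the pooled three-way interaction model
#' (`biomarker_change * sex * group`), the two stratified two-way models
#' (`biomarker_change * sex` within the preclinical-AD and MCI groups), and a
#' sensitivity model restricting MCI to biomarker-positive participants.
#' Covariates are baseline age (centred), education (centred) and APOE-e4
#' carrier status.
#'
#' @param cohort long-format cohort data frame (see [validate_cohort()] for
#'   the schema).
#' @param reference normative reference sample used to fit norms with
#'   [fit_norms()]; ignored when `norms` is supplied. Norms are never fit on
#'   the analytic cohort itself.
#' @param norms optional pre-fitted `"normative_models"` object.
#' @param cutpoint CSF ratio positivity cut-point.
#' @param sex_coding,group_coding indicator codings (defaults female = 1,
#'   MCI = 1).
#' @param reml estimate by REML (default) or ML.
#' @param min_visits participants with fewer visits are excluded (default 2,
#'   the minimum with a change score).
#' @return An object of class `"memdecline"` with elements `staging` (audit
#'   table), `labels`, `change` (change-score table), `baseline` (sex
#'   comparison table), `fits` (list `full`, `preclinical`, `mci`,
#'   `sensitivity`; an element is `NULL`, marked not run, when its sample is
#'   unavailable), `standardization`, `norms`, `config` and `n` (per-model
#'   sample sizes). Methods: `print`, `summary`, `coef`, `plot`, `residuals`,
#'   `predict`, `simulate`.
#' @examples
#' cfg <- cohort_config(n_per_cell = 30, seed = 7, mode = "raw")
#' cohort <- simulate_cohort(cfg, effect_preset("null"))
#' ref <- simulate_reference(n = 500, seed = 8)
#' fit <- memdecline(cohort, reference = ref)
#' coef(fit, "full")["biomarker_change:sex:group"]
#' @export
memdecline <- function(cohort, reference = NULL, norms = NULL, cutpoint = 0.025,
                       sex_coding = c(female = 1, male = 0),
                       group_coding = c(MCI = 1, preclinical = 0),
                       reml = TRUE, min_visits = 2L) {
  validate_cohort(cohort)
  if (is.null(norms)) {
    if (is.null(reference)) {
      stop("supply either a reference sample or pre-fitted norms; ",
           "norms are never fit on the analytic cohort", call. = FALSE)
    }
    norms <- fit_norms(reference, tests = staging_tests(), sex_coding = sex_coding)
  }
  staging <- stage_baseline(cohort, norms, cutpoint = cutpoint,
                            sex_coding = sex_coding)
  labels <- stats::setNames(staging$label, staging$pid)
  keep <- names(labels)[labels %in% c("preclinical_AD", "MCI")]
  visits_per <- table(cohort$pid)
  keep <- keep[visits_per[keep] >= min_visits]
  if (!length(keep)) {
    stop("no analysis groups: no preclinical-AD or MCI participants with ",
         "at least ", min_visits, " visits", call. = FALSE)
  }
  analytic <- cohort[cohort$pid %in% keep, , drop = FALSE]
  change <- build_change_table(analytic, labels = labels,
                               sex_coding = sex_coding, group_coding = group_coding)
  fits <- list(full = NULL, preclinical = NULL, mci = NULL, sensitivity = NULL)
  pre <- change[change$group_label == "preclinical", ]
  mci <- change[change$group_label == "MCI", ]
  if (nrow(pre) && nrow(mci)) fits$full <- fit_lmm(change, reml = reml)
  if (nrow(pre)) fits$preclinical <- fit_lmm(pre, stratified = TRUE, reml = reml)
  if (nrow(mci)) {
    fits$mci <- fit_lmm(mci, stratified = TRUE, reml = reml)
    positive <- stats::setNames(staging$positive, staging$pid)
    mci_pos <- mci[positive[mci$pid], ]
    if (nrow(mci_pos)) {
      fits$sensitivity <- fit_lmm(mci_pos, stratified = TRUE, reml = reml)
    }
  }
  baseline <- baseline_table(analytic, labels = labels,
                             standardization = attr(change, "standardization"))
  structure(list(
    staging = staging, labels = labels, change = change, baseline = baseline,
    fits = fits, standardization = attr(change, "standardization"),
    norms = norms,
    config = list(cutpoint = cutpoint, sex_coding = sex_coding,
                  group_coding = group_coding, reml = reml,
                  min_visits = min_visits),
    n = list(
      staged = nrow(staging),
      analytic = length(keep),
      preclinical = length(unique(pre$pid)),
      mci = length(unique(mci$pid))
    )
  ), class = "memdecline")
}

#' @export
print.memdecline <- function(x, ...) {
  cat("Biomarker-change / memory-decline analysis\n")
  cat(sprintf("Staged: %d participants; analytic sample: %d (%d preclinical AD, %d MCI)\n",
              x$n$staged, x$n$analytic, x$n$preclinical, x$n$mci))
  for (nm in names(x$fits)) {
    cat("\n==", nm, "model ==\n")
    if (is.null(x$fits[[nm]])) cat("not run\n") else print(x$fits[[nm]])
  }
  invisible(x)
}

#' @export
summary.memdecline <- function(object, ...) {
  key <- function(fit, term) {
    if (is.null(fit)) return(NULL)
    fit$coefficients[fit$coefficients$term == term, ]
  }
  out <- list(
    n = object$n,
    three_way = key(object$fits$full, "biomarker_change:sex:group"),
    sex_by_change_mci = key(object$fits$mci, "biomarker_change:sex"),
    sex_by_change_preclinical = key(object$fits$preclinical, "biomarker_change:sex"),
    icc = if (!is.null(object$fits$full)) object$fits$full$icc,
    baseline = object$baseline
  )
  class(out) <- "summary.memdecline"
  out
}

#' @export
print.summary.memdecline <- function(x, ...) {
  fmt <- function(row, label) {
    if (is.null(row) || !nrow(row)) return(invisible(NULL))
    cat(sprintf("%s: beta = %.2f, 95%% CI [%.2f, %.2f], p = %s\n", label,
                row$estimate, row$ci_low, row$ci_high,
                format.pval(row$p, digits = 2, eps = 1e-3)))
  }
  cat(sprintf("Analytic sample: %d participants (%d preclinical AD, %d MCI)\n",
              x$n$analytic, x$n$preclinical, x$n$mci))
  fmt(x$three_way, "sex x group x biomarker change (full model)")
  fmt(x$sex_by_change_preclinical, "sex x biomarker change (preclinical)")
  fmt(x$sex_by_change_mci, "sex x biomarker change (MCI)")
  if (!is.null(x$icc)) cat(sprintf("full-model ICC = %.2f\n", x$icc))
  invisible(x)
}

#' @export
coef.memdecline <- function(object, model = c("full", "preclinical", "mci",
                                              "sensitivity"), ...) {
  model <- match.arg(model)
  fit <- object$fits[[model]]
  if (is.null(fit)) stop("model '", model, "' was not run", call. = FALSE)
  coef(fit)
}

#' @export
residuals.memdecline <- function(object, model = "full", ...) {
  fit <- object$fits[[model]]
  if (is.null(fit)) stop("model '", model, "' was not run", call. = FALSE)
  stats::residuals(fit$model)
}

#' Predict expected memory change from the fitted fixed effects
#'
#' Population-level (random intercept set to zero) prediction from the chosen
#' model's fixed effects.
#'
#' @param object a `"memdecline"` fit.
#' @param newdata data frame with the model covariates (`biomarker_change`,
#'   `sex`, `group` for the full model, `age_c`, `edu_c`, `apoe4`).
#' @param model which fitted model to use.
#' @param ... unused.
#' @export
predict.memdecline <- function(object, newdata, model = "full", ...) {
  fit <- object$fits[[model]]
  if (is.null(fit)) stop("model '", model, "' was not run", call. = FALSE)
  stratified <- !"group" %in% all.vars(fit$formula)
  rhs <- if (stratified) "~ biomarker_change * sex + age_c + edu_c + apoe4"
         else "~ biomarker_change * sex * group + age_c + edu_c + apoe4"
  X <- stats::model.matrix(stats::as.formula(rhs), newdata)
  beta <- coef(fit)
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' Scatter of biomarker change against memory change by sex and group
#'
#' One panel per diagnostic group; per-sex least-squares lines summarize the
#' change-on-change association.
#'
#' @param x a `"memdecline"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.memdecline <- function(x, ...) {
  ch <- x$change
  groups <- intersect(c("preclinical", "MCI"), unique(ch$group_label))
  op <- graphics::par(mfrow = c(1, length(groups)))
  on.exit(graphics::par(op))
  cols <- c(female = "#3366BB", male = "#BB3333")
  for (g in groups) {
    d <- ch[ch$group_label == g, ]
    graphics::plot(d$biomarker_change, d$memory_change,
                   col = cols[d$sex_label], pch = 16, cex = 0.6,
                   xlab = "pTau181/Abeta42 change (lagged residual)",
                   ylab = "memory composite change (lagged residual)",
                   main = g, ...)
    for (s in c("female", "male")) {
      ds <- d[d$sex_label == s, ]
      if (nrow(ds) > 2) {
        graphics::abline(stats::lm(memory_change ~ biomarker_change, ds),
                         col = cols[s], lwd = 2)
      }
    }
    graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Simulate new cohorts from a fitted analysis
#'
#' Uses the fitted full-model fixed effects and variance components as
#' generative truth for [simulate_cohort()], enabling parametric-bootstrap
#' style checks of the estimator on cohorts shaped like the analysed one.
#'
#' @param object a `"memdecline"` fit with a full model.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param config optional [cohort_config()]; defaults to cells matching the
#'   analysed sample.
#' @param ... unused.
#' @return A list of `nsim` cohort data frames.
#' @export
simulate.memdecline <- function(object, nsim = 1, seed = 1L, config = NULL, ...) {
  fit <- object$fits$full
  if (is.null(fit)) stop("full model was not run; cannot simulate", call. = FALSE)
  eff <- true_effects(coef(fit)[.model_terms_full], fit$tau00, fit$sigma2)
  if (is.null(config)) {
    ch <- object$change
    base <- unique(ch[, c("pid", "sex_label", "group_label")])
    cells <- c(
      preclinical_female = sum(base$group_label == "preclinical" & base$sex_label == "female"),
      preclinical_male = sum(base$group_label == "preclinical" & base$sex_label == "male"),
      mci_female = sum(base$group_label == "MCI" & base$sex_label == "female"),
      mci_male = sum(base$group_label == "MCI" & base$sex_label == "male")
    )
    config <- cohort_config(cells = cells, seed = as.integer(seed))
  }
  lapply(seq_len(nsim), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed) + i - 1L
    simulate_cohort(cfg, eff)
  })
}
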