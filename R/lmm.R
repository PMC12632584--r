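# Random-intercept linear mixed models for change-on-change analysis, with
# Wald inference, variance components and the intraclass correlation.

#' Intraclass correlation from variance components
#'
#' `icc = tau00 / (tau00 + sigma2)`: the share of outcome variance
#' attributable to stable between-participant differences.
#'
#' @param tau00 between-participant intercept variance (>= 0).
#' @param sigma2 residual variance (> 0).
#' @return Fraction in `[0, 1)`.
#' @examples
#' icc(0.12, 0.56) # 0.1765
#' @export
icc <- function(tau00, sigma2) {
  if (any(!is.numeric(sigma2)) || any(sigma2 <= 0)) {
    stop("sigma2 must be positive", call. = FALSE)
  }
  if (any(tau00 < 0)) stop("tau00 must be non-negative", call. = FALSE)
  tau00 / (tau00 + sigma2)
}

#' Fit a random-intercept change-on-change model
#'
#' Fits `memory_change ~ biomarker_change * sex * group + age_c + edu_c +
#' apoe4 + (1 | pid)` (full model) or the single-group stratified version
#' without the group terms, by (restricted) maximum likelihood via
#' \pkg{lme4}. Inference is Wald: 95% CIs are `estimate +/- 1.96 * SE` and
#' p-values come from the Wald z statistic. Non-convergence is reported,
#' never silently accepted; a between-participant variance estimated at the
#' boundary (0) is returned with a warning.
#'
#' @param data a change table (see [build_change_table()]) with columns
#'   `memory_change`, `biomarker_change`, `sex`, `group` (full model only),
#'   `age_c`, `edu_c`, `apoe4`, `pid`.
#' @param stratified logical; drop the group terms (single-group model).
#' @param reml use REML (default) or ML.
#' @param covariates additional adjustment columns beyond the default
#'   `age_c + edu_c + apoe4`.
#' @return An object of class `"decline_lmm"`: list with `coefficients` (data
#'   frame: `term`, `estimate`, `se`, `ci_low`, `ci_high`, `p`), `sigma2`,
#'   `tau00`, `icc`, `n_participants`, `n_observations`, `converged`,
#'   `boundary`, `reml`, `formula` and the underlying `merMod` in `$model`.
#' @export
fit_lmm <- function(data, stratified = FALSE, reml = TRUE,
                    covariates = c("age_c", "edu_c", "apoe4")) {
  fixed <- if (stratified) "biomarker_change * sex" else "biomarker_change * sex * group"
  rhs <- paste(c(fixed, covariates), collapse = " + ")
  fml <- stats::as.formula(paste("memory_change ~", rhs, "+ (1 | pid)"))
  need <- c("memory_change", "biomarker_change", "sex", if (!stratified) "group",
            covariates, "pid")
  require_columns(data, need, "model data")
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  if (!stratified && length(unique(data$group)) < 2) {
    stop("full model needs both diagnostic groups; use stratified = TRUE for one group",
         call. = FALSE)
  }
  if (length(unique(data$sex)) < 2) {
    stop("degenerate stratum: only one sex present, the sex terms are unidentifiable",
         call. = FALSE)
  }
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    message = function(m) invokeRestart("muffleMessage")
  )
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(conv_msgs) || !length(conv_msgs)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau00 <- vc$vcov[vc$grp == "pid"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  boundary <- isTRUE(tau00 < 1e-8)
  if (boundary) {
    warning("between-participant variance estimated at the boundary (tau00 = 0)")
  }
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  zstat <- est / se
  coefs <- data.frame(
    term = rownames(cf), estimate = unname(est), se = unname(se),
    ci_low = unname(est - 1.96 * se), ci_high = unname(est + 1.96 * se),
    p = unname(2 * stats::pnorm(-abs(zstat))),
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  structure(list(
    coefficients = coefs, sigma2 = sigma2, tau00 = tau00,
    icc = icc(tau00, sigma2),
    n_participants = length(unique(data$pid)),
    n_observations = nrow(data),
    converged = converged, boundary = boundary, reml = reml,
    formula = fml, model = fit
  ), class = "decline_lmm")
}

#' @export
print.decline_lmm <- function(x, digits = 3, ...) {
  cat("Random-intercept model:", deparse(x$formula), "\n")
  cat(sprintf("%d observations from %d participants (%s)\n",
              x$n_observations, x$n_participants, if (x$reml) "REML" else "ML"))
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$ci <- sprintf(paste0("[%.", digits, "f, %.", digits, "f]"), tab$ci_low, tab$ci_high)
  tab$p <- format.pval(tab$p, digits = 2, eps = 1e-3)
  print.data.frame(tab[, c("term", "estimate", "ci", "p")], row.names = FALSE)
  cat(sprintf("sigma2 = %.3f, tau00 = %.3f, ICC = %.2f\n", x$sigma2, x$tau00, x$icc))
  invisible(x)
}

#' @export
coef.decline_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

# one-row Table-style export used by write_report()
lmm_as_table <- function(fit) {
  if (is.null(fit)) {
    return(data.frame(term = "not run", estimate = NA, se = NA, ci_low = NA,
                      ci_high = NA, p = NA))
  }
  tab <- fit$coefficients
  extra <- data.frame(
    term = c("sigma2", "tau00_id", "icc", "n_participants", "n_observations"),
    estimate = c(fit$sigma2, fit$tau00, fit$icc, fit$n_participants,
                 fit$n_observations),
    se = NA, ci_low = NA, ci_high = NA, p = NA
  )
  rbind(tab, extra)
}
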