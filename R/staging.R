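# Actuarial (Jak/Bondi-style) diagnostic staging: six tests, three cognitive
# domains, impairment flags in, baseline stage labels out.

#' Actuarial cognitive classification from impairment flags
#'
#' Applies the two actuarial MCI criteria to a complete six-test impairment
#' profile: a participant is MCI if (1) both tests within any one cognitive
#' domain are impaired, or (2) at least one test is impaired in each of the
#' three domains. Participants meeting neither criterion are cognitively
#' normal (CN). Dementia (an upstream input label, not adjudicated here)
#' excludes the participant.
#'
#' @param flags named logical vector (or single-row data frame) of impairment
#'   flags for the six tests `r paste(staging_tests(), collapse = ", ")`; all
#'   six must be present and non-missing.
#' @param dementia logical.
#' @return `"MCI"`, `"CN"`, or `"excluded"` (dementia).
#' @export
classify_jak_bondi <- function(flags, dementia = FALSE) {
  if (is.data.frame(flags)) flags <- unlist(flags[1, , drop = TRUE])
  miss <- setdiff(.staging_tests, names(flags))
  if (length(miss) || any(is.na(flags[.staging_tests]))) {
    stop("classification requires a complete six-test profile; missing: ",
         paste(c(miss, .staging_tests[is.na(flags[.staging_tests])]), collapse = ", "),
         call. = FALSE)
  }
  if (isTRUE(dementia)) return("excluded")
  f <- as.logical(flags[.staging_tests])
  names(f) <- .staging_tests
  per_domain <- vapply(.staging_domains, function(tests) sum(f[tests]), numeric(1))
  crit1 <- any(per_domain == 2)         # two impaired tests within a domain
  crit2 <- all(per_domain >= 1)         # one impaired test in every domain
  if (crit1 || crit2) "MCI" else "CN"
}

#' AD biomarker positivity
#'
#' Positive when the CSF pTau181/Abeta42 ratio is at or above the cut-point,
#' or when any supplied modality flag (e.g. amyloid or tau PET) is `TRUE` —
#' a logical OR across modalities. A ratio exactly at the cut-point counts
#' positive.
#'
#' @param ratio CSF pTau181/Abeta42 ratio (>= 0), possibly `NA`.
#' @param cutpoint ratio cut-point.
#' @param flags logical vector of additional modality positivity flags
#'   (optional; `NA`s ignored).
#' @return Logical.
#' @export
biomarker_positive <- function(ratio = NA_real_, cutpoint = 0.025, flags = logical(0)) {
  flags <- flags[!is.na(flags)]
  if ((length(ratio) == 0L || all(is.na(ratio))) && length(flags) == 0L) {
    stop("biomarker positivity needs a ratio or at least one modality flag",
         call. = FALSE)
  }
  if (any(ratio < 0, na.rm = TRUE)) stop("ratio must be >= 0", call. = FALSE)
  isTRUE(any(ratio >= cutpoint, na.rm = TRUE)) || any(as.logical(flags))
}

#' Stage a cohort at baseline
#'
#' Uses baseline-visit data only: z-scores the six staging tests against the
#' supplied norms, flags impairment (`z < -1`), applies
#' [classify_jak_bondi()], and splits cognitively normal participants into
#' preclinical AD (biomarker positive) versus biomarker-negative CN.
#'
#' @param cohort long-format cohort (see [validate_cohort()]).
#' @param norms a `"normative_models"` object covering the six staging tests.
#' @param cutpoint CSF ratio positivity cut-point.
#' @param sex_coding indicator coding for the normative regressions.
#' @param baseline_visit visit index treated as baseline (default 0).
#' @return A staging audit data frame, one row per participant: `pid`, the six
#'   z-scores (`z_*`), six impairment flags (`imp_*`), `criterion1`,
#'   `criterion2`, `dementia`, `positive`, and `label` in
#'   `{"preclinical_AD", "MCI", "CN_biomarker_negative", "excluded_dementia"}`.
#' @export
stage_baseline <- function(cohort, norms, cutpoint = 0.025,
                           sex_coding = c(female = 1, male = 0),
                           baseline_visit = 0L) {
  validate_cohort(cohort)
  stopifnot(inherits(norms, "normative_models"))
  miss_tests <- setdiff(.staging_tests, norms$test)
  if (length(miss_tests)) {
    stop("norms lack staging test(s): ", paste(miss_tests, collapse = ", "),
         call. = FALSE)
  }
  base <- cohort[cohort$visit == baseline_visit, , drop = FALSE]
  no_base <- setdiff(unique(cohort$pid), base$pid)
  if (length(no_base)) {
    stop("participant(s) lacking a baseline visit: ",
         paste(utils::head(no_base, 10), collapse = ", "), call. = FALSE)
  }
  audit <- data.frame(pid = base$pid, stringsAsFactors = FALSE)
  for (tst in .staging_tests) {
    m <- norms[norms$test == tst, ]
    z <- z_score(base[[tst]], base$age_baseline, base$sex, base$education, m,
                 sex_coding = sex_coding)
    audit[[paste0("z_", tst)]] <- z
    audit[[paste0("imp_", tst)]] <- flag_impaired(z)
  }
  imp <- as.matrix(audit[, paste0("imp_", .staging_tests)])
  colnames(imp) <- .staging_tests
  per_domain <- sapply(.staging_domains, function(tests) rowSums(imp[, tests, drop = FALSE]))
  if (is.null(dim(per_domain))) per_domain <- matrix(per_domain, nrow = 1)
  audit$criterion1 <- apply(per_domain == 2, 1, any)
  audit$criterion2 <- apply(per_domain >= 1, 1, all)
  audit$dementia <- as.logical(base$dementia)
  audit$positive <- vapply(seq_len(nrow(base)), function(i) {
    biomarker_positive(base$biomarker_ratio[i], cutpoint,
                       flags = as.logical(base$biomarker_positive[i]))
  }, logical(1))
  audit$label <- ifelse(audit$dementia, "excluded_dementia",
                 ifelse(audit$criterion1 | audit$criterion2, "MCI",
                 ifelse(audit$positive, "preclinical_AD", "CN_biomarker_negative")))
  if (all(audit$label == "excluded_dementia")) {
    warning("all participants excluded for dementia: empty analytic sample")
  }
  class(audit) <- c("staging_audit", "data.frame")
  audit
}

#' @export
print.staging_audit <- function(x, ...) {
  cat("Baseline actuarial staging of", nrow(x), "participants\n")
  print(table(x$label))
  invisible(x)
}
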