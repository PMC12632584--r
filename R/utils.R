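clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# inverse-CDF truncated normal draw
rtruncnorm1 <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a probability in [0, 1]", call. = FALSE)
  }
}

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(name, " must be a single positive number", call. = FALSE)
  }
}

#' Convert sex labels to the model indicator
#'
#' @param sex character vector of `"female"` / `"male"`.
#' @param coding named numeric vector giving the indicator value per label;
#'   default `c(female = 1, male = 0)`.
#' @return Numeric vector of indicator values.
#' @export
sex_indicator <- function(sex, coding = c(female = 1, male = 0)) {
  if (!setequal(names(coding), c("female", "male")) ||
      !setequal(unname(coding), c(0, 1))) {
    stop("sex coding must assign 0 and 1 to 'female' and 'male'", call. = FALSE)
  }
  bad <- !sex %in% names(coding)
  if (any(bad)) stop("unknown sex label(s): ", paste(unique(sex[bad]), collapse = ", "),
                     call. = FALSE)
  unname(coding[sex])
}

#' @rdname sex_indicator
#' @param group character vector of `"preclinical"` / `"MCI"`.
#' @export
group_indicator <- function(group, coding = c(MCI = 1, preclinical = 0)) {
  if (!setequal(names(coding), c("MCI", "preclinical")) ||
      !setequal(unname(coding), c(0, 1))) {
    stop("group coding must assign 0 and 1 to 'MCI' and 'preclinical'", call. = FALSE)
  }
  bad <- !group %in% names(coding)
  if (any(bad)) stop("unknown group label(s): ", paste(unique(group[bad]), collapse = ", "),
                     call. = FALSE)
  unname(coding[group])
}

require_columns <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
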