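# Independent oracles and shared fixtures, kept deliberately separate from
# the package's implementation paths.

# brute-force actuarial classification over an explicit 6-bit profile:
# positions 1:2 = speed/executive, 3:4 = language, 5:6 = memory.
brute_force_mci <- function(bits) {
  stopifnot(length(bits) == 6)
  d1 <- bits[1] + bits[2]
  d2 <- bits[3] + bits[4]
  d3 <- bits[5] + bits[6]
  (d1 == 2 || d2 == 2 || d3 == 2) || (d1 >= 1 && d2 >= 1 && d3 >= 1)
}

all_profiles <- function() {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  names(g) <- c("tmt_a", "tmt_b", "category_fluency", "boston_naming",
                "ravlt_delayed", "ravlt_recognition")
  g
}

# closed-form two-parameter OLS on (x, y)
ols_closed_form <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept,
       residuals = y - intercept - slope * x)
}

# tiny balanced random-intercept fixture: 4 participants x 2 observations,
# a within-participant regressor (0, 1) and a participant-level one; for this
# balanced design the GLS fixed-effect estimator with any compound-symmetric
# covariance coincides with OLS, giving a deterministic oracle.
balanced_fixture <- function() {
  data.frame(
    pid = rep(c("a", "b", "c", "d"), each = 2),
    visit = rep(1:2, 4),
    biomarker_change = rep(c(0, 1), 4),
    sex = rep(c(0, 0, 1, 1), each = 2),
    memory_change = c(1.0, 0.4, 2.0, 1.1, 0.2, -0.8, 0.5, -0.1)
  )
}

gls_fixed_cov <- function(X, y, pid, tau00, sigma2) {
  n <- length(y)
  V <- diag(sigma2, n)
  for (p in unique(pid)) {
    idx <- which(pid == p)
    V[idx, idx] <- V[idx, idx] + tau00
  }
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# small raw-mode cohort + reference shared across pipeline tests
make_small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_per_cell = 40, seed = 42, mode = "raw")
      cohort <- simulate_cohort(cfg, effect_preset("full"))
      ref <- simulate_reference(n = 1500, seed = 43)
      fit <- suppressWarnings(memdecline(cohort, reference = ref))
      cache <<- list(cfg = cfg, cohort = cohort, ref = ref, fit = fit)
    }
    cache
  }
})
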