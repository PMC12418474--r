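# Independent oracles and tiny fixture builders used across the suite.

# Leave-one-out Cook's distance: refit with sample i deleted and sum the
# squared change in fitted values, divided by p * s^2. Deliberately written
# against the definition, not the closed form the package uses.
loo_cooks <- function(x, y) {
  n <- length(x)
  full <- stats::lm(y ~ x)
  s2 <- sum(stats::residuals(full)^2) / (n - 2)
  yhat <- stats::fitted(full)
  vapply(seq_len(n), function(i) {
    fit_i <- stats::lm(y[-i] ~ x[-i])
    yhat_i <- stats::coef(fit_i)[1] + stats::coef(fit_i)[2] * x
    sum((yhat - yhat_i)^2) / (2 * s2)
  }, numeric(1))
}

# Closed-form simple-regression coefficients, independent of lm.
ols_by_hand <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  e <- y - a - b * x
  ss_tot <- sum((y - mean(y))^2)
  list(
    slope = b, intercept = a, r2 = 1 - sum(e^2) / ss_tot,
    slope_se = sqrt(sum(e^2) / (length(x) - 2) / sum((x - mean(x))^2))
  )
}

# Build a matched cohort directly from aligned serum/plasma value matrices.
make_cohort <- function(serum_vals, plasma_vals, label = "test") {
  n <- nrow(serum_vals)
  ids <- sprintf("S%02d", seq_len(n))
  sm <- npx_matrix(
    tibble::as_tibble(cbind(tibble::tibble(sample_id = ids), tibble::as_tibble(serum_vals))),
    medium = "serum"
  )
  pm <- npx_matrix(
    tibble::as_tibble(cbind(tibble::tibble(sample_id = ids), tibble::as_tibble(plasma_vals))),
    medium = "plasma"
  )
  pair_matched(sm, pm, cohort_label = label)
}

# One-protein cohort from two vectors.
make_cohort1 <- function(x, y, protein = "P1", label = "test") {
  make_cohort(
    matrix(x, ncol = 1, dimnames = list(NULL, protein)),
    matrix(y, ncol = 1, dimnames = list(NULL, protein)),
    label = label
  )
}

# Small long-format NPX file on disk; returns the path.
write_long_fixture <- function(rows, path = withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())) {
  readr::write_csv(rows, path)
  path
}

# Noise SD giving a target expected R2 for slope s and predictor SD sx:
# r2 = s^2 sx^2 / (s^2 sx^2 + sigma^2).
noise_for_r2 <- function(slope, sx, r2) abs(slope) * sx * sqrt((1 - r2) / r2)
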