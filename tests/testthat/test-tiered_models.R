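test_that("fit_ols matches the closed-form least-squares solution", {
  f <- fit_ols(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r2, 1)

  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  f <- fit_ols(x, y)
  expect_equal(f$slope, 0.6)
  expect_equal(f$intercept, 1.0)
  expect_equal(f$r2, 0.36)
  # s^2 = SSE/(n-2) = 1.6, Sxx = 5 => se = sqrt(0.32)
  expect_equal(f$slope_se, sqrt(1.6 / 5), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    xr <- rnorm(12)
    yr <- 0.8 * xr + rnorm(12, sd = 0.5)
    fr <- fit_ols(xr, yr)
    or <- ols_by_hand(xr, yr)
    expect_equal(fr$slope, or$slope, tolerance = 1e-12)
    expect_equal(fr$intercept, or$intercept, tolerance = 1e-12)
    expect_equal(fr$r2, or$r2, tolerance = 1e-12)
    expect_equal(fr$slope_se, or$slope_se, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are handled as specified", {
  expect_error(fit_ols(rep(1, 5), 1:5), class = "npx_degenerate_error")
  f <- fit_ols(1:5, rep(2, 5))
  expect_equal(f$slope, 0)
  expect_equal(f$r2, 0)
  expect_true(f$degenerate)
  expect_error(fit_ols(c(1, 2), c(1, 2)), class = "npx_degenerate_error")
})

test_that("Cook's distance: zero for perfect fits, flags the gross outlier", {
  f <- fit_ols(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_equal(cooks_distance(f), rep(0, 4))

  x <- c(0, 1, 2, 3)
  y <- c(0, 1, 2, 10)
  d <- cooks_distance(fit_ols(x, y))
  expect_equal(which.max(d), 4L)
  expect_equal(which.max(loo_cooks(x, y)), 4L)
})

test_that("closed-form Cook's distance equals the leave-one-out definition", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:25, 1)
    x <- rnorm(n)
    y <- 1 + 0.9 * x + rnorm(n, sd = 0.4)
    d <- cooks_distance(fit_ols(x, y))
    expect_equal(d, loo_cooks(x, y), tolerance = 1e-10)
    # and agrees with the reference implementation in stats
    expect_equal(d, unname(stats::cooks.distance(stats::lm(y ~ x))), tolerance = 1e-10)
  }
})

test_that("outlier ranking is by distance, deterministic under ties", {
  expect_equal(rank_outliers(c(0.1, 0.9, 0.2, 0.05), 1, c("a", "b", "c", "d")), "b")
  # tie at the k-th rank: the earlier-listed sample wins
  expect_equal(
    rank_outliers(c(0.5, 0.9, 0.5, 0.1, 0.2), 2, c("a", "b", "c", "d", "e")),
    c("b", "a")
  )
  # removals must leave a fittable regression (at least 3 samples)
  expect_error(rank_outliers(c(1, 2, 3), 1, c("a", "b", "c")), class = "npx_parameter_error")
  d <- runif(19)
  expect_equal(
    rank_outliers(d, 3),
    order(-d)[1:3]
  )
})

test_that("tiered_fit accepts the first adequate tier and records exclusions", {
  set.seed(101)
  x <- rnorm(19, 5, 1.5)
  y_clean <- 0.9 * x + 0.2 + rnorm(19, sd = 0.15)
  f1 <- tiered_fit(x, y_clean, sprintf("S%02d", 1:19))
  expect_equal(f1$tier, 1L)
  expect_equal(f1$excluded_samples[[1]], character(0))
  expect_equal(f1$n_used, 19L)

  # two grossly displaced points push Tier-1 R2 below threshold
  y <- y_clean
  y[c(4, 12)] <- y[c(4, 12)] + 9
  f2 <- tiered_fit(x, y, sprintf("S%02d", 1:19))
  expect_equal(f2$tier, 2L)
  expect_setequal(f2$excluded_samples[[1]], c("S04", "S12"))
  expect_equal(f2$n_used, 17L)
  # oracle: refit without the displaced points
  oracle <- ols_by_hand(x[-c(4, 12)], y[-c(4, 12)])
  expect_equal(f2$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(f2$r2, oracle$r2, tolerance = 1e-12)
})

test_that("tier-3 removals are a superset of tier-2 removals (tier-1 ranking)", {
  set.seed(202)
  x <- rnorm(19, 5, 1.5)
  y <- 0.9 * x + rnorm(19, sd = 0.2)
  y[c(3, 9, 15)] <- y[c(3, 9, 15)] + c(10, -9, 8)
  f <- tiered_fit(x, y, sprintf("S%02d", 1:19))
  expect_equal(f$tier, 3L)
  d1 <- cooks_distance(fit_ols(x, y))
  expect_equal(f$excluded_samples[[1]], sprintf("S%02d", order(-d1)[1:3]))
  expect_setequal(f$excluded_samples[[1]], c("S03", "S09", "S15"))
})

test_that("a protein failing all tiers keeps the Tier-1 fit for inspection", {
  set.seed(303)
  x <- rnorm(19, 5, 1.5)
  y <- rnorm(19)
  f <- tiered_fit(x, y, sprintf("S%02d", 1:19))
  expect_true(is.na(f$tier))
  expect_equal(f$reason, "below_r2_threshold")
  expect_equal(f$n_used, 19L)
  expect_equal(f$slope, ols_by_hand(x, y)$slope, tolerance = 1e-12)
})

test_that("fraction-based removal counts reproduce 2 and 3 at n = 19", {
  sch <- tier_scheme()
  expect_equal(unname(removal_counts(sch, 19)), c(2, 3))
  expect_equal(unname(removal_counts(sch, 40)), c(4, 6))
  fixed <- tier_scheme(removal = "fixed")
  expect_equal(unname(removal_counts(fixed, 40)), c(2, 3))
})

test_that("confidence half-width follows the t distribution", {
  # perfect fit: zero standard error, zero half-width
  f <- fit_ols(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_equal(ci_halfwidth(f$slope_se, f$n), 0)

  f <- fit_ols(c(1, 2, 3, 4), c(2, 1, 4, 3))
  hw <- ci_halfwidth(f$slope_se, 4, alpha = 0.05)
  expect_equal(hw, stats::qt(0.975, 2) * sqrt(0.32), tolerance = 1e-12)
  expect_equal(hw, 2.4339, tolerance = 1e-4)
  expect_error(ci_halfwidth(0.1, 2), class = "npx_parameter_error")
})

test_that("pearson screen is descriptive, signed, and NA-safe", {
  x <- c(1, 2, 3, 4, 5)
  cohort <- make_cohort(
    cbind(A = x, B = x, C = rep(1, 5)),
    cbind(A = x, B = -x, C = x)
  )
  scr <- pearson_screen(cohort, threshold = 0.5)
  expect_equal(scr$pearson_r[scr$protein_id == "A"], 1)
  expect_true(scr$pearson_pass[scr$protein_id == "A"])
  expect_equal(scr$pearson_r[scr$protein_id == "B"], -1)
  expect_false(scr$pearson_pass[scr$protein_id == "B"]) # threshold on signed r
  expect_true(is.na(scr$pearson_r[scr$protein_id == "C"]))
  expect_false(scr$pearson_pass[scr$protein_id == "C"])

  # the screen does not restrict fitting: all proteins are fitted anyway
  fits <- fit_tiered_models(cohort)
  expect_equal(nrow(fits), 3)
})

test_that("rescaling the predictor rescales the slope and preserves R2", {
  set.seed(55)
  x <- rnorm(19, 5, 1.5)
  y <- 0.8 * x + rnorm(19, sd = 0.4)
  base <- tiered_fit(x, y)
  for (a in c(2, -0.5, 10)) {
    tr <- tiered_fit(a * x + 3, y)
    expect_equal(tr$slope, base$slope / a, tolerance = 1e-8)
    expect_equal(tr$r2, base$r2, tolerance = 1e-8)
  }
})

test_that("identical inputs give bit-identical fit collections", {
  sim <- gen_matched_cohort(sim_config(n_proteins = 30, seed = 9))
  f1 <- fit_tiered_models(sim$cohort)
  f2 <- fit_tiered_models(sim$cohort)
  expect_identical(tibble::as_tibble(f1), tibble::as_tibble(f2))
})

test_that("variance diagnostics: constants fail, location shifts do not matter", {
  x <- c(1, 2, 3, 4, 5, 2.5, 3.5)
  cohort <- make_cohort(
    cbind(A = x, B = rep(2, 7)),
    cbind(A = 2 * x + rnorm(7, sd = 0.01), B = rep(3, 7))
  )
  fits <- fit_tiered_models(cohort)
  diag <- variance_diagnostics(cohort, fits)
  expect_equal(diag$serum_variance[diag$protein_id == "B"], 0)
  expect_false(diag$modelable[diag$protein_id == "B"])

  shifted <- make_cohort(
    cbind(A = x + 7),
    cbind(A = cohort$plasma$A + 7)
  )
  fshift <- fit_tiered_models(shifted)
  expect_equal(fshift$tier, fits$tier[fits$protein_id == "A"])
  expect_equal(fshift$r2, fits$r2[fits$protein_id == "A"], tolerance = 1e-9)
})

test_that("modelability is higher in the high-variance stratum", {
  sim <- gen_matched_cohort(sim_config(
    n_proteins = 150, low_var_fraction = 0.4, seed = 31
  ))
  fits <- fit_tiered_models(sim$cohort)
  joined <- dplyr::inner_join(
    tibble::as_tibble(fits)[c("protein_id", "tier")],
    sim$truth[c("protein_id", "low_variance")],
    by = "protein_id"
  )
  frac_hi <- mean(!is.na(joined$tier[!joined$low_variance]))
  frac_lo <- mean(!is.na(joined$tier[joined$low_variance]))
  expect_gt(frac_hi, frac_lo)
})
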