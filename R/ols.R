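#' Simple least-squares fit of plasma on serum
#'
#' Ordinary least squares of `y` on `x` for one protein, returning everything
#' the tier scheme needs: slope, intercept, slope standard error, R-squared,
#' residuals and hat-matrix leverages. Pairs with a missing value on either
#' side are dropped first.
#'
#' @param x Predictor NPX vector (serum under the default orientation).
#' @param y Response NPX vector (plasma).
#' @return A list with elements `slope`, `intercept`, `slope_se`, `r2`,
#'   `residuals`, `fitted`, `leverages`, `sigma2` (residual variance,
#'   SSE/(n-2)), `n`, `used` (logical index of complete pairs in the input)
#'   and `degenerate`. A constant `y` yields slope 0 with `r2` defined as 0
#'   and `degenerate = TRUE`; a constant `x` is an error since no slope is
#'   identifiable.
#' @export
fit_ols <- function(x, y) {
  used <- is.finite(x) & is.finite(y)
  xs <- x[used]
  ys <- y[used]
  n <- length(xs)
  if (n < 3) abort_degenerate("fewer than 3 complete pairs")
  sxx <- sum((xs - mean(xs))^2)
  if (sxx == 0) abort_degenerate("predictor has zero variance; slope not identifiable")
  h <- 1 / n + (xs - mean(xs))^2 / sxx
  if (sum((ys - mean(ys))^2) == 0) {
    return(list(
      slope = 0, intercept = mean(ys), slope_se = 0, r2 = 0,
      residuals = rep(0, n), fitted = ys, leverages = h,
      sigma2 = 0, ss_tot = 0, n = n, used = used, degenerate = TRUE
    ))
  }
  fit <- stats::lm(ys ~ xs)
  sm <- suppressWarnings(summary(fit)) # silence "essentially perfect fit"
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_se = unname(sm$coefficients[2, 2]),
    r2 = sm$r.squared,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    leverages = h,
    sigma2 = sm$sigma^2,
    ss_tot = sum((ys - mean(ys))^2),
    n = n,
    used = used,
    degenerate = FALSE
  )
}

#' Cook's distance for a simple regression fit
#'
#' Influence of each observation on the fitted line:
#' \deqn{D_i = \frac{e_i^2}{p\,s^2}\cdot\frac{h_{ii}}{(1-h_{ii})^2}}
#' with p = 2 estimated parameters, s^2 = SSE/(n-2) and h the hat-diagonal.
#' This closed form equals the leave-one-out definition
#' \eqn{\sum_j (\hat y_j - \hat y_{j(i)})^2 / (p s^2)}.
#'
#' @param fit A [fit_ols()] result.
#' @return Nonnegative distances, one per used pair. A perfect fit (all
#'   residuals zero) gives all-zero distances; a leverage of exactly 1 gives
#'   `Inf`.
#' @export
cooks_distance <- function(fit) {
  h <- fit$leverages
  # an (up to rounding) exact fit has no influential points; without this
  # guard, residuals of order 1e-16 would produce O(1) distances
  sse <- fit$sigma2 * (fit$n - 2)
  perfect <- fit$sigma2 == 0 ||
    (!is.null(fit$ss_tot) && fit$ss_tot > 0 && sse / fit$ss_tot < 1e-20)
  if (perfect) {
    return(ifelse(h >= 1 - 1e-12, Inf, 0))
  }
  d <- fit$residuals^2 / (2 * fit$sigma2) * h / (1 - h)^2
  d[h >= 1 - 1e-12] <- Inf
  d
}

#' Rank the most influential samples
#'
#' The `k` samples with the largest Cook's distance, in descending order of
#' distance; ties are broken by input order (the earlier-listed sample wins),
#' so the ranking is deterministic.
#'
#' @param distances Per-sample Cook's distances.
#' @param k Number of samples to select; must leave at least 3 samples
#'   (`k < n - 2`).
#' @param ids Sample identifiers aligned with `distances` (default: indices).
#' @return Character (or integer) vector of the `k` selected identifiers.
#' @export
rank_outliers <- function(distances, k, ids = seq_along(distances)) {
  n <- length(distances)
  if (length(ids) != n) abort_parameter("ids and distances lengths differ")
  if (k >= n - 2) abort_parameter("k must be < n - 2 so a regression remains fittable")
  if (k <= 0) return(ids[0])
  ord <- order(-distances) # stable: ties keep input order
  ids[ord[seq_len(k)]]
}

#' Confidence half-width of a fitted slope
#'
#' Two-sided t-based half-width: `qt(1 - alpha/2, n - 2) * slope_se`. The
#' "CI" reported throughout the package (and gated at 0.3) is this scalar
#' half-width, i.e. the interval is slope +/- half-width.
#'
#' @param slope_se Standard error of the slope.
#' @param n_used Number of pairs used in the fit (df = n_used - 2).
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return The half-width; an error if `n_used <= 2`.
#' @export
ci_halfwidth <- function(slope_se, n_used, alpha = 0.05) {
  if (any(n_used <= 2)) abort_parameter("confidence interval undefined for n_used <= 2")
  stats::qt(1 - alpha / 2, df = n_used - 2) * slope_se
}
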