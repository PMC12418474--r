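#' Tier scheme configuration
#'
#' Parameters of the tiered modelling fallback: Tier 1 fits all pairs; if its
#' R-squared falls below `r2_threshold`, Tier 2 removes the most influential
#' samples (by Cook's distance from the Tier-1 fit) and refits; Tier 3
#' removes a larger, nested set. A protein failing all three tiers is
#' non-modelable.
#'
#' @param r2_threshold Modelability threshold on R-squared (default 0.5).
#' @param pearson_threshold Descriptive screen threshold on the signed
#'   Pearson correlation (default 0.5); the screen never blocks fitting.
#' @param removal `"fraction"` (default) removes `ceiling(tier2_frac * n)` and
#'   `ceiling(tier3_frac * n)` samples — 2 and 3 at n = 19; `"fixed"` removes
#'   `tier2_count` and `tier3_count` regardless of n.
#' @param tier2_frac,tier3_frac Fractions of n removed at Tiers 2 and 3.
#' @param tier2_count,tier3_count Fixed removal counts used when
#'   `removal = "fixed"`.
#' @param ranking_basis `"tier1"` (default) ranks all removals by the Tier-1
#'   fit's Cook's distances, making Tier-3 removals a superset of Tier-2;
#'   `"per_tier"` re-ranks the Tier-3 additions using the Tier-2 fit.
#' @param alpha Significance level for the slope confidence half-width.
#' @return A list of class `tier_scheme`.
#' @export
tier_scheme <- function(r2_threshold = 0.5, pearson_threshold = 0.5,
                        removal = c("fraction", "fixed"),
                        tier2_frac = 0.10, tier3_frac = 0.15,
                        tier2_count = 2, tier3_count = 3,
                        ranking_basis = c("tier1", "per_tier"),
                        alpha = 0.05) {
  removal <- match.arg(removal)
  ranking_basis <- match.arg(ranking_basis)
  if (r2_threshold < 0 || r2_threshold > 1) abort_parameter("r2_threshold must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) abort_parameter("alpha must be in (0, 1)")
  if (removal == "fraction" && tier3_frac <= tier2_frac) {
    abort_parameter("tier3_frac must exceed tier2_frac")
  }
  if (removal == "fixed" && tier3_count <= tier2_count) {
    abort_parameter("tier3_count must exceed tier2_count")
  }
  structure(
    list(
      r2_threshold = r2_threshold, pearson_threshold = pearson_threshold,
      removal = removal, tier2_frac = tier2_frac, tier3_frac = tier3_frac,
      tier2_count = tier2_count, tier3_count = tier3_count,
      ranking_basis = ranking_basis, alpha = alpha
    ),
    class = "tier_scheme"
  )
}

removal_counts <- function(scheme, n) {
  if (scheme$removal == "fraction") {
    c(k2 = ceiling(scheme$tier2_frac * n), k3 = ceiling(scheme$tier3_frac * n))
  } else {
    c(k2 = scheme$tier2_count, k3 = scheme$tier3_count)
  }
}

tier_fit_row <- function(protein_id, tier, fit, n_total, excluded, alpha,
                         reason = NA_character_) {
  if (is.null(fit)) {
    return(tibble::tibble(
      protein_id = protein_id, tier = NA_integer_,
      slope = NA_real_, intercept = NA_real_, slope_se = NA_real_,
      r2 = NA_real_, n_total = n_total, n_used = NA_integer_,
      excluded_samples = list(character(0)),
      ci_halfwidth = NA_real_, degenerate = TRUE, reason = reason
    ))
  }
  tibble::tibble(
    protein_id = protein_id,
    tier = tier,
    slope = fit$slope,
    intercept = fit$intercept,
    slope_se = fit$slope_se,
    r2 = fit$r2,
    n_total = n_total,
    n_used = fit$n,
    excluded_samples = list(as.character(excluded)),
    ci_halfwidth = if (fit$n > 2) ci_halfwidth(fit$slope_se, fit$n, alpha) else NA_real_,
    degenerate = fit$degenerate,
    reason = reason
  )
}

#' Fit one protein through the tier scheme
#'
#' Runs the three-tier fallback for a single protein's matched serum/plasma
#' values. Tier 1 uses every complete pair; Tiers 2 and 3 drop the top-k2 and
#' top-k3 Cook's-distance-ranked samples (ranking from the Tier-1 fit by
#' default) and refit. The first tier reaching the R-squared threshold is
#' accepted. A protein failing all tiers is returned with `tier = NA` and the
#' Tier-1 fit's statistics, so its (inadequate) slope remains inspectable.
#'
#' @param x Serum (predictor) NPX values.
#' @param y Plasma (response) NPX values, same subjects.
#' @param sample_ids Subject identifiers aligned with `x`/`y`.
#' @param scheme A [tier_scheme()].
#' @param protein_id Identifier recorded on the returned row.
#' @return A one-row tibble with the accepted tier's slope, intercept,
#'   standard error, R-squared, n, excluded samples, confidence half-width
#'   and a `reason` column explaining non-modelable outcomes.
#' @export
tiered_fit <- function(x, y, sample_ids = seq_along(x), scheme = tier_scheme(),
                       protein_id = "protein") {
  used <- is.finite(x) & is.finite(y)
  n_total <- sum(used)
  ids <- as.character(sample_ids)[used]
  xs <- x[used]
  ys <- y[used]
  ks <- removal_counts(scheme, n_total)

  if (n_total < 3 + ks["k3"]) {
    return(tier_fit_row(protein_id, NA_integer_, NULL, n_total, NULL,
      scheme$alpha,
      reason = "insufficient_pairs"
    ))
  }
  t1 <- tryCatch(fit_ols(xs, ys), npx_degenerate_error = function(e) NULL)
  if (is.null(t1)) {
    return(tier_fit_row(protein_id, NA_integer_, NULL, n_total, NULL,
      scheme$alpha,
      reason = "degenerate_predictor"
    ))
  }
  if (!t1$degenerate && t1$r2 >= scheme$r2_threshold) {
    return(tier_fit_row(protein_id, 1L, t1, n_total, character(0), scheme$alpha))
  }

  d1 <- cooks_distance(t1)
  excl2 <- rank_outliers(d1, ks["k2"], ids)
  keep2 <- !(ids %in% excl2)
  t2 <- tryCatch(fit_ols(xs[keep2], ys[keep2]), npx_degenerate_error = function(e) NULL)
  if (!is.null(t2) && !t2$degenerate && t2$r2 >= scheme$r2_threshold) {
    return(tier_fit_row(protein_id, 2L, t2, n_total, excl2, scheme$alpha))
  }

  if (scheme$ranking_basis == "tier1" || is.null(t2)) {
    excl3 <- rank_outliers(d1, ks["k3"], ids)
  } else {
    d2 <- cooks_distance(t2)
    extra <- rank_outliers(d2, ks["k3"] - ks["k2"], ids[keep2])
    excl3 <- c(excl2, extra)
  }
  keep3 <- !(ids %in% excl3)
  t3 <- tryCatch(fit_ols(xs[keep3], ys[keep3]), npx_degenerate_error = function(e) NULL)
  if (!is.null(t3) && !t3$degenerate && t3$r2 >= scheme$r2_threshold) {
    return(tier_fit_row(protein_id, 3L, t3, n_total, excl3, scheme$alpha))
  }

  # non-modelable: report the all-data fit for inspection
  tier_fit_row(protein_id, NA_integer_, t1, n_total, character(0),
    scheme$alpha,
    reason = "below_r2_threshold"
  )
}

#' Fit the tier scheme across a matched cohort
#'
#' Applies [tiered_fit()] to every protein in a [pair_matched()] cohort and
#' joins the descriptive Pearson screen and per-medium variance/mean
#' diagnostics. Fitting is applied to all proteins regardless of the Pearson
#' screen outcome.
#'
#' @param cohort A `matched_cohort`.
#' @param scheme A [tier_scheme()].
#' @return A tibble of class `tier_fits`, one row per protein, with columns
#'   `protein_id, tier, slope, intercept, slope_se, r2, n_total, n_used,
#'   excluded_samples (list), ci_halfwidth, degenerate, reason, pearson_r,
#'   pearson_pass, serum_variance, plasma_variance, mean_serum, mean_plasma,
#'   mean_npx`. The scheme and cohort label travel as attributes. A protein
#'   is modelable iff `!is.na(tier)`.
#' @export
fit_tiered_models <- function(cohort, scheme = tier_scheme()) {
  stopifnot(inherits(cohort, "matched_cohort"))
  prots <- npx_proteins(cohort$serum)
  subj <- cohort$subjects$subject
  fits <- purrr::map(prots, function(pr) {
    tiered_fit(cohort$serum[[pr]], cohort$plasma[[pr]],
      sample_ids = subj, scheme = scheme, protein_id = pr
    )
  })
  fits <- dplyr::bind_rows(fits)
  scr <- pearson_screen(cohort, threshold = scheme$pearson_threshold)
  diag <- cohort_moments(cohort)
  out <- dplyr::left_join(fits, scr, by = "protein_id")
  out <- dplyr::left_join(out, diag, by = "protein_id")
  structure(out,
    scheme = scheme, cohort_label = cohort$cohort_label,
    class = c("tier_fits", class(tibble::tibble()))
  )
}

#' Descriptive Pearson screen
#'
#' Signed Pearson correlation between each protein's serum and plasma values
#' over complete pairs, flagged against a threshold. The screen describes how
#' much of the panel behaves linearly; it does not restrict which proteins
#' enter tiered fitting.
#'
#' @param cohort A `matched_cohort`.
#' @param threshold Pass threshold on the signed correlation (default 0.5).
#' @return Tibble with `protein_id`, `pearson_r` (NA when either medium has
#'   zero variance or fewer than 3 complete pairs) and `pearson_pass`.
#' @export
pearson_screen <- function(cohort, threshold = 0.5) {
  stopifnot(inherits(cohort, "matched_cohort"))
  prots <- npx_proteins(cohort$serum)
  r <- vapply(prots, function(pr) {
    x <- cohort$serum[[pr]]
    y <- cohort$plasma[[pr]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  tibble::tibble(
    protein_id = prots,
    pearson_r = unname(r),
    pearson_pass = !is.na(r) & r >= threshold
  )
}

cohort_moments <- function(cohort) {
  prots <- npx_proteins(cohort$serum)
  purrr::map_dfr(prots, function(pr) {
    x <- cohort$serum[[pr]]
    y <- cohort$plasma[[pr]]
    ok <- is.finite(x) & is.finite(y)
    tibble::tibble(
      protein_id = pr,
      serum_variance = if (sum(ok) > 1) stats::var(x[ok]) else NA_real_,
      plasma_variance = if (sum(ok) > 1) stats::var(y[ok]) else NA_real_,
      mean_serum = if (any(ok)) mean(x[ok]) else NA_real_,
      mean_plasma = if (any(ok)) mean(y[ok]) else NA_real_,
      mean_npx = if (any(ok)) mean(c(x[ok], y[ok])) else NA_real_
    )
  })
}

#' Variance and expression diagnostics for fitted proteins
#'
#' Joins per-protein, per-medium sample variances and mean NPX to tier
#' outcomes, supporting the variance-vs-R-squared and
#' expression-vs-modelability diagnostics: modelability tracks within-cohort
#' variance, not expression level.
#'
#' @param cohort A `matched_cohort`.
#' @param fits A `tier_fits` table from [fit_tiered_models()] for the same
#'   cohort.
#' @return Tibble with `protein_id, serum_variance, plasma_variance,
#'   mean_serum, mean_plasma, mean_npx, r2, tier, modelable`.
#' @export
variance_diagnostics <- function(cohort, fits) {
  diag <- cohort_moments(cohort)
  dplyr::left_join(
    diag,
    dplyr::select(
      tibble::as_tibble(fits), "protein_id", "r2", "tier"
    ),
    by = "protein_id"
  ) |>
    dplyr::mutate(modelable = !is.na(.data$tier))
}

#' @export
print.tier_fits <- function(x, ...) {
  cat(sprintf(
    "<tier_fits '%s'> %d proteins: %d tier-1, %d tier-2, %d tier-3, %d non-modelable\n",
    attr(x, "cohort_label") %||% "?", nrow(x),
    sum(x$tier == 1L, na.rm = TRUE), sum(x$tier == 2L, na.rm = TRUE),
    sum(x$tier == 3L, na.rm = TRUE), sum(is.na(x$tier))
  ))
  NextMethod()
}

#' Tidy a tier-fits table
#'
#' @param x A `tier_fits` object.
#' @param ... Unused.
#' @return The per-protein fit table as a plain tibble with the
#'   `excluded_samples` list-column flattened to a `;`-separated string.
#' @method tidy tier_fits
#' @export
tidy.tier_fits <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$excluded_samples <- vapply(out$excluded_samples, paste, character(1), collapse = ";")
  out
}

#' One-row summary of a tier-fits table
#'
#' @param x A `tier_fits` object.
#' @param ... Unused.
#' @return Tibble with protein counts per tier, the modelable total and
#'   fraction, the Pearson pass count, and the median R-squared among
#'   modelable proteins.
#' @method glance tier_fits
#' @export
glance.tier_fits <- function(x, ...) {
  mod <- !is.na(x$tier)
  tibble::tibble(
    n_proteins = nrow(x),
    n_tier1 = sum(x$tier == 1L, na.rm = TRUE),
    n_tier2 = sum(x$tier == 2L, na.rm = TRUE),
    n_tier3 = sum(x$tier == 3L, na.rm = TRUE),
    n_modelable = sum(mod),
    frac_modelable = mean(mod),
    n_pearson_pass = sum(x$pearson_pass, na.rm = TRUE),
    median_r2_modelable = stats::median(x$r2[mod])
  )
}
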