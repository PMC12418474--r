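#' Refit catalogued proteins in an independent cohort
#'
#' Runs the tier scheme on exactly the catalog proteins that the new cohort
#' measures; catalog proteins absent from the cohort's panel are reported as
#' untestable rather than fitted.
#'
#' @param catalog A `factor_catalog` derived from another cohort.
#' @param cohort A `matched_cohort` from the validation study.
#' @param scheme A [tier_scheme()] (defaults match the discovery settings).
#' @return A `tier_fits` table over the intersection, with attribute
#'   `untestable` listing catalog proteins the cohort does not measure.
#' @export
refit_cohort <- function(catalog, cohort, scheme = tier_scheme()) {
  stopifnot(inherits(catalog, "factor_catalog"), inherits(cohort, "matched_cohort"))
  panel <- npx_proteins(cohort$serum)
  testable <- intersect(catalog$protein_id, panel)
  if (!length(testable)) {
    abort_integrity("the cohort measures none of the catalogued proteins")
  }
  fits <- fit_tiered_models(subset_cohort(cohort, testable), scheme = scheme)
  attr(fits, "untestable") <- setdiff(catalog$protein_id, panel)
  fits
}

#' Cross-cohort slope concordance
#'
#' Pairs proteins modelable in both fit collections and calls them concordant
#' when the absolute slope difference is within the tolerance (inclusive).
#' Proteins modelable on one side only are counted separately, with the
#' non-modelable side's per-medium variances attached — low within-cohort
#' variance is the usual reason a previously modelable protein fails to
#' refit.
#'
#' @param fits_a,fits_b `tier_fits` tables sharing a protein namespace.
#' @param tolerance Maximum absolute slope difference (default 0.3, the same
#'   magnitude as the CI gate).
#' @return A tibble of class `concordance_report` over the shared proteins
#'   with `slope_a, slope_b, modelable_a, modelable_b, abs_delta, concordant`
#'   plus both sides' variances; summary counts are in the `summary`
#'   attribute and via [glance.concordance_report()].
#' @export
slope_concordance <- function(fits_a, fits_b, tolerance = 0.3) {
  if (!is.numeric(tolerance) || tolerance < 0) {
    abort_parameter("tolerance must be nonnegative")
  }
  a <- concordance_side(fits_a, "a")
  b <- concordance_side(fits_b, "b")
  shared <- dplyr::inner_join(a, b, by = "protein_id")
  if (!nrow(shared)) abort_integrity("the two fit collections share no proteins")
  shared <- shared |>
    dplyr::mutate(
      abs_delta = ifelse(.data$modelable_a & .data$modelable_b,
        abs(.data$slope_a - .data$slope_b), NA_real_
      ),
      concordant = .data$modelable_a & .data$modelable_b &
        !is.na(.data$abs_delta) & .data$abs_delta <= tolerance
    )
  smry <- list(
    n_shared = nrow(shared),
    n_overlap_modelable = sum(shared$modelable_a & shared$modelable_b),
    n_concordant = sum(shared$concordant),
    n_lost_a_only = sum(shared$modelable_a & !shared$modelable_b),
    n_lost_b_only = sum(!shared$modelable_a & shared$modelable_b),
    tolerance = tolerance
  )
  structure(shared,
    summary = smry, tolerance = tolerance,
    class = c("concordance_report", class(tibble::tibble()))
  )
}

concordance_side <- function(fits, suffix) {
  tbl <- tibble::as_tibble(fits)
  need <- c("protein_id", "slope", "tier", "serum_variance", "plasma_variance")
  if (!all(c("protein_id", "slope") %in% names(tbl))) {
    abort_format("fit collections need 'protein_id' and 'slope' columns")
  }
  for (col in setdiff(need, names(tbl))) tbl[[col]] <- NA_real_
  out <- tbl[need]
  out$modelable <- !is.na(tbl$tier)
  names(out) <- c(
    "protein_id", paste0("slope_", suffix), paste0("tier_", suffix),
    paste0("serum_variance_", suffix), paste0("plasma_variance_", suffix),
    paste0("modelable_", suffix)
  )
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<concordance_report> %d shared proteins; %d modelable in both, %d concordant (|dslope| <= %s)\n",
    s$n_shared, s$n_overlap_modelable, s$n_concordant, format(s$tolerance)
  ))
  NextMethod()
}

#' One-row summary of a concordance report
#'
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return Tibble with the shared/overlap/concordant counts, losses per
#'   side, the concordant fraction among proteins modelable in both cohorts,
#'   and the tolerance used.
#' @method glance concordance_report
#' @export
glance.concordance_report <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(
    n_shared = s$n_shared,
    n_overlap_modelable = s$n_overlap_modelable,
    n_concordant = s$n_concordant,
    frac_concordant = ifelse(s$n_overlap_modelable > 0,
      s$n_concordant / s$n_overlap_modelable, NA_real_
    ),
    n_lost_a_only = s$n_lost_a_only,
    n_lost_b_only = s$n_lost_b_only,
    tolerance = s$tolerance
  )
}

#' Membership table and Venn-region counts for modelable-protein sets
#'
#' @param sets A named list of two or more protein-ID character vectors
#'   (e.g. the modelable sets of several cohorts).
#' @return A list with `membership` (tibble: protein_id plus one logical
#'   column per set) and `regions` (tibble: one row per occupied intersection
#'   region, the region named by the sets it belongs to, counts summing to
#'   the union size).
#' @export
overlap_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    abort_parameter("sets must be a list of at least two protein-ID vectors")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  all_ids <- sort(unique(unlist(sets)))
  membership <- tibble::tibble(protein_id = all_ids)
  for (nm in names(sets)) membership[[nm]] <- all_ids %in% sets[[nm]]
  pattern <- apply(as.matrix(membership[names(sets)]), 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  counts <- table(pattern)
  regions <- tibble::tibble(
    region = names(counts),
    count = as.integer(counts)
  ) |> dplyr::arrange(dplyr::desc(.data$count))
  list(membership = membership, regions = regions)
}
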