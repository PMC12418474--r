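#' Gate fitted slopes into a transformation-factor catalog
#'
#' Retains the modelable fits whose 95% slope confidence half-width does not
#' exceed the gate (inclusive boundary: a half-width exactly at the threshold
#' is kept). The slope of each retained fit becomes that protein's
#' transformation factor; the intercept is carried for provenance only and is
#' never used for conversion, since it reflects cohort-specific scaling.
#'
#' @param fits A `tier_fits` table from [fit_tiered_models()] (non-modelable
#'   rows are filtered out here).
#' @param max_halfwidth Gate on the confidence half-width (default 0.3).
#' @param direction Which way the factors convert; under the default
#'   regression orientation the slope maps serum NPX onto the plasma scale.
#' @return A tibble of class `factor_catalog` with one row per retained
#'   protein (`protein_id, slope, intercept, slope_se, ci_halfwidth, r2,
#'   tier, n_used, excluded_samples, cohort_label, direction`) and attributes
#'   `gate_threshold` and `provenance`.
#' @export
gate_by_ci <- function(fits, max_halfwidth = 0.3,
                       direction = c("serum_to_plasma", "plasma_to_serum")) {
  direction <- match.arg(direction)
  if (!is.numeric(max_halfwidth) || max_halfwidth < 0) {
    abort_parameter("max_halfwidth must be a nonnegative number")
  }
  x <- tibble::as_tibble(fits)
  label <- attr(fits, "cohort_label") %||% "cohort"
  if (!"cohort_label" %in% names(x)) x$cohort_label <- label
  kept <- dplyr::filter(
    x,
    !is.na(.data$tier), !.data$degenerate,
    !is.na(.data$ci_halfwidth), .data$ci_halfwidth <= max_halfwidth
  )
  out <- dplyr::transmute(
    kept,
    protein_id = .data$protein_id,
    slope = .data$slope,
    intercept = .data$intercept,
    slope_se = .data$slope_se,
    ci_halfwidth = .data$ci_halfwidth,
    r2 = .data$r2,
    tier = .data$tier,
    n_used = .data$n_used,
    excluded_samples = .data$excluded_samples,
    cohort_label = .data$cohort_label,
    direction = direction
  )
  out <- tibble::as_tibble(as.list(out)) # drop attributes inherited from fits
  new_factor_catalog(out, gate_threshold = max_halfwidth,
                     provenance = unique(out$cohort_label))
}

new_factor_catalog <- function(tbl, gate_threshold, provenance) {
  if (anyDuplicated(tbl$protein_id)) {
    abort_integrity("a factor catalog holds one factor per protein")
  }
  structure(tbl,
    gate_threshold = gate_threshold,
    provenance = provenance,
    class = c("factor_catalog", class(tibble::tibble()))
  )
}

#' @export
print.factor_catalog <- function(x, ...) {
  cat(sprintf(
    "<factor_catalog> %d transformation factors (CI gate <= %s; cohorts: %s)\n",
    nrow(x), format(attr(x, "gate_threshold")),
    paste(attr(x, "provenance"), collapse = ", ")
  ))
  NextMethod()
}

#' Histogram of fitted slopes
#'
#' Counts slopes in bins that are closed on the left and open on the right,
#' except the final bin which is closed on both ends, so every slope inside
#' the covered range is counted exactly once.
#'
#' @param x A `tier_fits` table, `factor_catalog`, or numeric slope vector.
#'   Tier-fits input is restricted to modelable proteins.
#' @param bin_edges Strictly increasing bin edges.
#' @return Tibble with `bin_lo`, `bin_hi`, `count`.
#' @seealso [count_slope_range()] for a single closed interval such as
#'   \[0.75, 1\].
#' @export
slope_distribution <- function(x, bin_edges = seq(0, 2, by = 0.25)) {
  s <- extract_slopes(x)
  if (!length(s)) abort_parameter("no slopes to bin")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort_parameter("bin_edges must be strictly increasing")
  }
  nb <- length(bin_edges) - 1
  counts <- vapply(seq_len(nb), function(i) {
    lo <- bin_edges[i]
    hi <- bin_edges[i + 1]
    if (i < nb) sum(s >= lo & s < hi) else sum(s >= lo & s <= hi)
  }, integer(1))
  tibble::tibble(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    count = counts
  )
}

#' Count slopes in a closed interval
#'
#' @inheritParams slope_distribution
#' @param lower,upper Closed interval bounds (both ends inclusive).
#' @return Integer count.
#' @export
count_slope_range <- function(x, lower = 0.75, upper = 1) {
  s <- extract_slopes(x)
  sum(s >= lower & s <= upper)
}

extract_slopes <- function(x) {
  if (is.numeric(x)) return(x[is.finite(x)])
  tbl <- tibble::as_tibble(x)
  if (!"slope" %in% names(tbl)) abort_format("input has no 'slope' column")
  s <- if ("tier" %in% names(tbl)) tbl$slope[!is.na(tbl$tier)] else tbl$slope
  s[is.finite(s)]
}

#' Apply transformation factors to an NPX matrix
#'
#' Converts each catalogued protein's NPX values to the target medium's scale
#' by multiplying by its factor (NPX is log2, so this is a power-law
#' relation on the linear scale; no linear-scale mode is offered). Intercepts
#' are deliberately not applied.
#'
#' @param matrix An [npx_matrix()] whose medium matches the catalog
#'   direction's source medium ("unknown" proceeds with a warning).
#' @param catalog A `factor_catalog`.
#' @param mode `"strict"` (default) drops proteins without a factor so
#'   transformed and untransformed scales are never mixed silently;
#'   `"passthrough"` copies them unchanged and lists them in the
#'   `untransformed_proteins` attribute.
#' @return An `npx_matrix` labelled with the target medium and a
#'   `transformed` attribute.
#' @export
apply_transform <- function(matrix, catalog, mode = c("strict", "passthrough")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "npx_matrix"), inherits(catalog, "factor_catalog"))
  dir <- unique(catalog$direction)
  if (length(dir) != 1) abort_integrity("catalog mixes transformation directions")
  source_medium <- if (dir == "serum_to_plasma") "serum" else "plasma"
  target_medium <- if (dir == "serum_to_plasma") "plasma" else "serum"
  med <- npx_medium(matrix)
  if (med == "unknown") {
    rlang::warn(paste0("matrix medium is 'unknown'; assuming ", source_medium))
  } else if (med != source_medium) {
    abort_usage(paste0(
      "catalog direction ", dir, " expects a ", source_medium,
      " matrix, got ", med
    ))
  }
  prots <- npx_proteins(matrix)
  shared <- intersect(prots, catalog$protein_id)
  if (!length(shared) && mode == "strict") {
    abort_integrity("no catalogued protein is present in the matrix")
  }
  out <- tibble::as_tibble(matrix)
  slopes <- stats::setNames(catalog$slope, catalog$protein_id)
  for (pr in shared) out[[pr]] <- out[[pr]] * slopes[[pr]]
  extra <- setdiff(prots, shared)
  if (mode == "strict") {
    out <- out[c("sample_id", shared)]
    extra <- character(0)
  }
  res <- npx_matrix(out, medium = target_medium)
  attr(res, "transformed") <- TRUE
  attr(res, "untransformed_proteins") <- extra
  res
}

#' Merge factor candidates across cohorts, keeping the best-fitting model
#'
#' For proteins catalogued in more than one cohort, the factor from the model
#' with the highest R-squared wins; ties go to the larger n, then to the
#' earlier-listed cohort. Proteins catalogued in a single cohort pass
#' through.
#'
#' @param ... Two or more `factor_catalog` objects (or a single list of
#'   them), sharing a protein-ID namespace.
#' @return A `factor_catalog` whose provenance lists every contributing
#'   cohort; the gate threshold is the maximum of the inputs' thresholds.
#' @export
select_best_factor <- function(...) {
  cats <- list(...)
  if (length(cats) == 1 && !inherits(cats[[1]], "factor_catalog")) cats <- cats[[1]]
  if (length(cats) < 1) abort_parameter("at least one catalog is required")
  stopifnot(all(vapply(cats, inherits, logical(1), "factor_catalog")))
  stacked <- dplyr::bind_rows(
    purrr::imap(cats, function(ct, i) dplyr::mutate(tibble::as_tibble(ct), .order = i))
  )
  best <- stacked |>
    dplyr::arrange(.data$protein_id, dplyr::desc(.data$r2),
                   dplyr::desc(.data$n_used), .data$.order) |>
    dplyr::distinct(.data$protein_id, .keep_all = TRUE) |>
    dplyr::select(-".order")
  new_factor_catalog(
    best,
    gate_threshold = max(vapply(cats, function(ct) attr(ct, "gate_threshold") %||% NA_real_, numeric(1))),
    provenance = unique(unlist(lapply(cats, attr, "provenance")))
  )
}
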