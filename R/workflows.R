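#' Fit workflow: matched cohort files to a gated factor catalog
#'
#' Reads a serum and a plasma NPX file, pairs them, fits the tier scheme,
#' gates by the CI half-width and writes the per-protein fits, the gated
#' catalog, the Pearson screen, the variance diagnostics and a reproducibility
#' manifest (input hashes, parameters, package version) to `out_dir`.
#'
#' @param serum_path,plasma_path NPX files (long or wide format).
#' @param map_path Optional TSV/CSV with columns `serum_id`, `plasma_id`;
#'   when `NULL`, samples sharing an identifier are paired.
#' @param out_dir Output directory, created if needed.
#' @param format `"long"` or `"wide"` NPX input.
#' @param scheme A [tier_scheme()].
#' @param ci_gate Gate on the slope CI half-width.
#' @param cohort_label Provenance label.
#' @param cols Long-format column mapping ([npx_cols()]).
#' @return Invisibly, a list with `fits`, `catalog`, and output `paths`.
#' @export
run_fit_workflow <- function(serum_path, plasma_path, map_path = NULL,
                             out_dir = ".", format = c("long", "wide"),
                             scheme = tier_scheme(), ci_gate = 0.3,
                             cohort_label = "cohort", cols = npx_cols()) {
  format <- match.arg(format)
  reader <- if (format == "long") {
    function(p, m) read_npx_long(p, medium = m, cols = cols)
  } else {
    function(p, m) read_npx_wide(p, medium = m)
  }
  serum <- reader(serum_path, "serum")
  plasma <- reader(plasma_path, "plasma")
  subject_map <- if (!is.null(map_path)) read_delim_sniffed(map_path) else NULL
  cohort <- pair_matched(serum, plasma, subject_map, cohort_label = cohort_label)

  fits <- fit_tiered_models(cohort, scheme = scheme)
  catalog <- gate_by_ci(fits, max_halfwidth = ci_gate)
  diag <- variance_diagnostics(cohort, fits)
  screen <- pearson_screen(cohort, threshold = scheme$pearson_threshold)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fits = file.path(out_dir, "fits.tsv"),
    catalog = file.path(out_dir, "catalog.tsv"),
    pearson = file.path(out_dir, "pearson_screen.tsv"),
    diagnostics = file.path(out_dir, "variance_diagnostics.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_tsv(tidy.tier_fits(fits), paths$fits)
  write_factor_table(catalog, paths$catalog)
  readr::write_tsv(screen, paths$pearson)
  readr::write_tsv(diag, paths$diagnostics)
  write_manifest(paths$manifest,
    inputs = c(serum = serum_path, plasma = plasma_path, map = map_path %||% NA),
    params = c(unclass(scheme), list(ci_gate = ci_gate, cohort_label = cohort_label))
  )
  invisible(list(fits = fits, catalog = catalog, paths = paths))
}

#' Multi-cohort pipeline: fit, concordance, best-factor selection
#'
#' Fits each cohort, gates each, keeps the proteins whose gated slopes are
#' pairwise concordant (|delta slope| within `tolerance`) across every pair
#' of cohorts that model them, and selects the best-R-squared factor per
#' protein among the concordant set. Proteins gated in a single cohort only
#' are excluded from the final catalog: cross-cohort support is the point of
#' the pipeline.
#'
#' @param cohorts A list of `matched_cohort` objects (>= 2).
#' @param scheme A [tier_scheme()].
#' @param ci_gate CI half-width gate.
#' @param tolerance Cross-cohort slope concordance tolerance.
#' @param out_dir Optional output directory; when given, writes the final
#'   catalog and per-cohort fit tables.
#' @return A list: `final` (`factor_catalog`), `fits` (per-cohort
#'   `tier_fits`), `concordance` (`concordance_report` list, one per cohort
#'   pair).
#' @export
run_pipeline_workflow <- function(cohorts, scheme = tier_scheme(),
                                  ci_gate = 0.3, tolerance = 0.3,
                                  out_dir = NULL) {
  if (!is.list(cohorts) || length(cohorts) < 2) {
    abort_usage("the pipeline needs at least two matched cohorts")
  }
  stopifnot(all(vapply(cohorts, inherits, logical(1), "matched_cohort")))
  fits <- lapply(cohorts, fit_tiered_models, scheme = scheme)
  catalogs <- lapply(fits, gate_by_ci, max_halfwidth = ci_gate)

  pairs <- utils::combn(length(fits), 2, simplify = FALSE)
  reports <- lapply(pairs, function(ij) {
    tryCatch(
      slope_concordance(fits[[ij[1]]], fits[[ij[2]]], tolerance = tolerance),
      npx_integrity_error = function(e) NULL
    )
  })
  names(reports) <- vapply(pairs, paste, character(1), collapse = "_vs_")

  discordant <- unique(unlist(lapply(reports, function(rep) {
    if (is.null(rep)) return(character(0))
    rep$protein_id[rep$modelable_a & rep$modelable_b & !rep$concordant]
  })))
  multi <- table(unlist(lapply(catalogs, function(ct) unique(ct$protein_id))))
  supported <- names(multi)[multi >= 2]
  keep <- setdiff(supported, discordant)
  trimmed <- lapply(catalogs, function(ct) {
    sub <- tibble::as_tibble(ct)[ct$protein_id %in% keep, ]
    new_factor_catalog(sub,
      gate_threshold = attr(ct, "gate_threshold"),
      provenance = attr(ct, "provenance")
    )
  })
  final <- select_best_factor(trimmed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_factor_table(final, file.path(out_dir, "final_catalog.tsv"))
    for (i in seq_along(fits)) {
      readr::write_tsv(
        tidy.tier_fits(fits[[i]]),
        file.path(out_dir, sprintf("fits_cohort%d.tsv", i))
      )
    }
  }
  list(final = final, fits = fits, concordance = reports)
}

write_manifest <- function(path, inputs, params) {
  hashes <- vapply(inputs, function(p) {
    if (is.na(p) || !file.exists(p)) NA_character_ else unname(tools::md5sum(p))
  }, character(1))
  jsonlite::write_json(
    list(
      package = "npxfactors",
      version = as.character(utils::packageVersion("npxfactors")),
      timestamp = format(Sys.time(), tz = "UTC"),
      inputs = as.list(inputs),
      input_md5 = as.list(hashes),
      parameters = params
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, null = "null", na = "null"
  )
  invisible(path)
}
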