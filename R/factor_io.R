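factor_table_cols <- c(
  "protein_id", "slope", "intercept", "slope_se", "ci_halfwidth",
  "r2", "tier", "n_used", "excluded_samples", "cohort_label"
)

#' Write a factor catalog to TSV
#'
#' Columns: protein_id, slope, intercept, slope_se, ci_halfwidth, r2, tier,
#' n_used, excluded_samples (`;`-separated), cohort_label, direction. Floats
#' are serialized at full precision, so a written-then-read catalog is
#' value-identical well beyond 6 significant digits.
#'
#' @param catalog A `factor_catalog` (may be empty: a header-only file is
#'   written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_factor_table <- function(catalog, path) {
  stopifnot(inherits(catalog, "factor_catalog"))
  tbl <- tibble::as_tibble(catalog)
  tbl$excluded_samples <- vapply(tbl$excluded_samples, paste, character(1), collapse = ";")
  readr::write_tsv(tbl[c(factor_table_cols, "direction")], path)
  invisible(path)
}

#' Read a factor catalog from TSV
#'
#' Inverse of [write_factor_table()]; any schema-compatible table (the ten
#' core columns, extras allowed) is accepted. A missing `direction` column
#' defaults to serum-to-plasma.
#'
#' @param path Path to a TSV written by [write_factor_table()].
#' @return A `factor_catalog`.
#' @export
read_factor_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(factor_table_cols, names(tbl))
  if (length(missing)) {
    abort_format(paste0(
      "factor table missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!"direction" %in% names(tbl)) tbl$direction <- "serum_to_plasma"
  tbl$tier <- as.integer(tbl$tier)
  tbl$n_used <- as.integer(tbl$n_used)
  tbl$excluded_samples <- lapply(
    as.character(tbl$excluded_samples),
    function(s) if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  )
  tbl$cohort_label <- as.character(tbl$cohort_label)
  new_factor_catalog(
    tibble::as_tibble(tbl[c(factor_table_cols, "direction")]),
    gate_threshold = if (nrow(tbl)) max(tbl$ci_halfwidth) else NA_real_,
    provenance = unique(tbl$cohort_label[!is.na(tbl$cohort_label)])
  )
}
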