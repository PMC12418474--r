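#' Pair matched serum and plasma samples into a cohort
#'
#' Aligns a serum and a plasma [npx_matrix()] on subject identity so that row
#' i of both matrices refers to the same person. Proteins are restricted to
#' the intersection of the two panels, and proteins with zero overlapping
#' non-missing (serum, plasma) pairs are dropped with a warning. Pairing never
#' fabricates values: every cell in the cohort traces to exactly one input
#' cell.
#'
#' @param serum,plasma [npx_matrix()] objects for the two media.
#' @param subject_map A data frame with columns `serum_id` and `plasma_id`
#'   (one row per subject), or `NULL` to pair samples sharing the same
#'   identifier in both matrices.
#' @param cohort_label Free-text provenance label carried onto fits and
#'   factors derived from this cohort.
#' @return A `matched_cohort`: a list with elements `serum`, `plasma`
#'   (row-aligned `npx_matrix` objects over the common panel), `subjects`
#'   (tibble of subject, serum_id, plasma_id) and `cohort_label`.
#' @export
pair_matched <- function(serum, plasma, subject_map = NULL,
                         cohort_label = "cohort") {
  stopifnot(inherits(serum, "npx_matrix"), inherits(plasma, "npx_matrix"))
  if (nrow(serum) == 0 || nrow(plasma) == 0) {
    abort_integrity("both matrices must be nonempty")
  }
  if (is.null(subject_map)) {
    common <- intersect(npx_samples(serum), npx_samples(plasma))
    if (!length(common)) abort_mapping("no shared sample identifiers and no subject_map given")
    subject_map <- tibble::tibble(serum_id = common, plasma_id = common)
  }
  subject_map <- tibble::as_tibble(subject_map)
  if (!all(c("serum_id", "plasma_id") %in% names(subject_map))) {
    abort_format("subject_map needs columns 'serum_id' and 'plasma_id'")
  }
  if (nrow(subject_map) == 0) abort_mapping("subject_map is empty")
  miss_s <- setdiff(subject_map$serum_id, npx_samples(serum))
  miss_p <- setdiff(subject_map$plasma_id, npx_samples(plasma))
  if (length(miss_s) || length(miss_p)) {
    abort_mapping(paste0(
      "subject_map references unknown sample IDs: ",
      paste(c(miss_s, miss_p), collapse = ", ")
    ))
  }
  if (nrow(subject_map) < 3) {
    abort_integrity("at least 3 matched subjects are required for any regression")
  }
  panel <- intersect(npx_proteins(serum), npx_proteins(plasma))
  if (!length(panel)) abort_integrity("the serum and plasma panels share no proteins")

  s <- tibble::as_tibble(serum)[match(subject_map$serum_id, serum$sample_id), c("sample_id", panel)]
  p <- tibble::as_tibble(plasma)[match(subject_map$plasma_id, plasma$sample_id), c("sample_id", panel)]

  # subjects are labelled by the serum-side ID
  n_pairs <- vapply(panel, function(pr) sum(!is.na(s[[pr]]) & !is.na(p[[pr]])), integer(1))
  dead <- panel[n_pairs == 0]
  if (length(dead)) {
    rlang::warn(paste0(
      length(dead), " protein(s) dropped: no overlapping non-missing pairs (",
      paste(utils::head(dead, 5), collapse = ", "),
      if (length(dead) > 5) ", ..." else "", ")"
    ))
    panel <- setdiff(panel, dead)
    if (!length(panel)) abort_integrity("no protein has any complete serum/plasma pair")
    s <- s[c("sample_id", panel)]
    p <- p[c("sample_id", panel)]
  }

  structure(
    list(
      serum = npx_matrix(s, medium = "serum"),
      plasma = npx_matrix(p, medium = "plasma"),
      subjects = tibble::tibble(
        subject = subject_map$serum_id,
        serum_id = subject_map$serum_id,
        plasma_id = subject_map$plasma_id
      ),
      cohort_label = cohort_label
    ),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf(
    "<matched_cohort '%s'> %d subjects x %d proteins\n",
    x$cohort_label, nrow(x$subjects), length(npx_proteins(x$serum))
  ))
  invisible(x)
}

#' Restrict a matched cohort to a protein subset
#'
#' @param cohort A `matched_cohort`.
#' @param proteins Character vector of protein IDs to keep; IDs absent from
#'   the cohort are ignored (callers wanting them reported use the returned
#'   panel).
#' @return A `matched_cohort` over the intersection.
#' @export
subset_cohort <- function(cohort, proteins) {
  stopifnot(inherits(cohort, "matched_cohort"))
  keep <- intersect(npx_proteins(cohort$serum), proteins)
  if (!length(keep)) abort_integrity("no requested protein is measured in this cohort")
  cohort$serum <- cohort$serum[c("sample_id", keep)]
  cohort$plasma <- cohort$plasma[c("sample_id", keep)]
  cohort
}
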