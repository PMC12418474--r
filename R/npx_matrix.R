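#' Construct an NPX matrix
#'
#' An `npx_matrix` is a tibble holding one cohort's Olink measurements in wide
#' orientation: a `sample_id` character column followed by one numeric column
#' per protein, values on the NPX (log2) scale. The blood medium the samples
#' came from ("serum", "plasma" or "unknown") travels with the object as an
#' attribute so downstream steps can refuse to transform the wrong medium.
#'
#' @param data A data frame whose first column is the sample identifier and
#'   whose remaining columns are numeric NPX values, one column per protein.
#'   Missing values are allowed and propagate; non-numeric protein columns are
#'   an error rather than being coerced silently.
#' @param medium One of `"serum"`, `"plasma"`, `"unknown"`.
#' @param sample_col Name of the sample identifier column (default: the first
#'   column).
#' @return A tibble of class `npx_matrix` with a `medium` attribute.
#' @examples
#' m <- npx_matrix(
#'   data.frame(sample_id = c("s1", "s2"), IL6 = c(5.1, 6.2), TNF = c(3.0, NA)),
#'   medium = "serum"
#' )
#' npx_proteins(m)
#' @export
npx_matrix <- function(data, medium = c("unknown", "serum", "plasma"),
                       sample_col = NULL) {
  medium <- match.arg(medium)
  data <- tibble::as_tibble(data)
  if (ncol(data) < 2) {
    abort_format("an NPX matrix needs a sample column and at least one protein column")
  }
  if (is.null(sample_col)) sample_col <- names(data)[1]
  if (!sample_col %in% names(data)) {
    abort_format(paste0("sample column '", sample_col, "' not found"))
  }
  data <- dplyr::relocate(data, dplyr::all_of(sample_col))
  names(data)[1] <- "sample_id"
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) {
    abort_integrity("duplicated sample identifiers")
  }
  prot <- names(data)[-1]
  if (anyDuplicated(prot)) {
    abort_integrity("duplicated protein identifiers")
  }
  bad <- prot[!vapply(data[prot], is.numeric, logical(1))]
  if (length(bad)) {
    abort_format(paste0(
      "non-numeric NPX column(s): ", paste(bad, collapse = ", "),
      " (values must be numeric or NA)"
    ))
  }
  inf <- prot[vapply(data[prot], function(v) any(is.infinite(v) | is.nan(v)), logical(1))]
  if (length(inf)) {
    abort_format(paste0("non-finite NPX values in: ", paste(inf, collapse = ", ")))
  }
  structure(data,
    medium = medium,
    class = c("npx_matrix", class(tibble::tibble()))
  )
}

#' @rdname npx_matrix
#' @param x An `npx_matrix`.
#' @export
npx_medium <- function(x) attr(x, "medium") %||% "unknown"

#' @rdname npx_matrix
#' @export
npx_proteins <- function(x) setdiff(names(x), "sample_id")

#' @rdname npx_matrix
#' @export
npx_samples <- function(x) x$sample_id

# keep class + medium through dplyr-style single-bracket subsetting
#' @export
`[.npx_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "sample_id" %in% names(out)) {
    attr(out, "medium") <- attr(x, "medium")
    class(out) <- class(x)
  }
  out
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf(
    "<npx_matrix> %d samples x %d proteins, medium = %s%s\n",
    nrow(x), length(npx_proteins(x)), npx_medium(x),
    if (isTRUE(attr(x, "transformed"))) " (transformed)" else ""
  ))
  NextMethod()
}

#' Default long-format column mapping
#'
#' Olink exports vary across software versions; these are the conventional
#' column names. Override individual entries to match a given export dialect.
#'
#' @param sample,protein,npx,qc Column names in the long file for the sample
#'   identifier, the protein/assay identifier used to key proteins, the NPX
#'   value, and the optional QC warning flag.
#' @return A named list consumed by [read_npx_long()].
#' @export
npx_cols <- function(sample = "SampleID", protein = "OlinkID",
                     npx = "NPX", qc = "QC_Warning") {
  list(sample = sample, protein = protein, npx = npx, qc = qc)
}

#' Read long-format NPX data
#'
#' Reads a delimited (CSV/TSV, delimiter sniffed) long-format Olink table with
#' one row per sample x assay and pivots it to a wide [npx_matrix()]. Rows
#' carrying a QC warning are retained but recorded in the `qc_flags`
#' attribute; filtering is the caller's choice since Olink QC semantics vary.
#'
#' @param path Path to the delimited file.
#' @param medium Medium label recorded on the returned matrix.
#' @param cols Column mapping from [npx_cols()]; protein identity is keyed on
#'   the single column named there (OlinkID vs UniProt reconciliation is out
#'   of scope).
#' @return An [npx_matrix()]. Duplicate (sample, protein) rows are an
#'   integrity error; missing mandatory columns are a format error naming the
#'   column.
#' @export
read_npx_long <- function(path, medium = c("unknown", "serum", "plasma"),
                          cols = npx_cols()) {
  medium <- match.arg(medium)
  raw <- read_delim_sniffed(path)
  for (key in c("sample", "protein", "npx")) {
    if (!cols[[key]] %in% names(raw)) {
      abort_format(paste0("missing mandatory column '", cols[[key]], "'"))
    }
  }
  long <- tibble::tibble(
    sample_id = as.character(raw[[cols$sample]]),
    protein_id = as.character(raw[[cols$protein]]),
    npx = suppressWarnings(as.numeric(raw[[cols$npx]]))
  )
  non_num <- !is.na(raw[[cols$npx]]) & is.na(long$npx) &
    !toupper(trimws(as.character(raw[[cols$npx]]))) %in% c("NA", "")
  if (any(non_num)) {
    abort_format("non-numeric NPX values; refusing to coerce silently")
  }
  dup <- duplicated(long[c("sample_id", "protein_id")])
  if (any(dup)) {
    abort_integrity(paste0(
      "duplicated (sample, protein) rows, e.g. (",
      long$sample_id[dup][1], ", ", long$protein_id[dup][1], ")"
    ))
  }
  wide <- tidyr::pivot_wider(long,
    names_from = "protein_id", values_from = "npx"
  )
  out <- npx_matrix(wide, medium = medium)
  if (cols$qc %in% names(raw)) {
    flagged <- !is.na(raw[[cols$qc]]) &
      !tolower(trimws(as.character(raw[[cols$qc]]))) %in% c("", "pass", "no warning", "false", "0")
    attr(out, "qc_flags") <- tibble::tibble(
      sample_id = long$sample_id[flagged],
      protein_id = long$protein_id[flagged]
    )
  }
  out
}

#' Read wide-format NPX data
#'
#' First column is the sample identifier, remaining columns one protein each.
#'
#' @inheritParams read_npx_long
#' @return An [npx_matrix()].
#' @export
read_npx_wide <- function(path, medium = c("unknown", "serum", "plasma")) {
  medium <- match.arg(medium)
  npx_matrix(read_delim_sniffed(path), medium = medium)
}

#' Write an NPX matrix in long format
#'
#' Inverse of [read_npx_long()] (missing cells are omitted from the file, so
#' read-then-write round-trips exactly).
#'
#' @param x An [npx_matrix()].
#' @param path Output path.
#' @param cols Column mapping from [npx_cols()].
#' @return `path`, invisibly.
#' @export
write_npx_long <- function(x, path, cols = npx_cols()) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x), -"sample_id",
    names_to = "protein_id", values_to = "npx"
  )
  long <- dplyr::filter(long, !is.na(.data$npx))
  names(long) <- c(cols$sample, cols$protein, cols$npx)
  readr::write_csv(long, path)
  invisible(path)
}

read_delim_sniffed <- function(path) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
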