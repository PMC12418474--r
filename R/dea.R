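#' Two-group differential expression analysis on NPX values
#'
#' Per-protein two-sided two-sample test between the groups, with
#' Benjamini-Hochberg adjustment across all scored proteins. A protein is
#' significant when its adjusted p-value passes the p gate AND its absolute
#' effect passes the effect gate; since NPX is log2-scale, the default effect
#' gate of 1 NPX unit corresponds to a 2-fold change.
#'
#' @param matrix An [npx_matrix()].
#' @param group_labels Per-sample two-level labels, aligned with the matrix
#'   rows (or named by sample_id). The effect is mean(second level) -
#'   mean(first level); levels are taken from the factor, or sorted unique
#'   values.
#' @param p_threshold Gate on the BH-adjusted p-value (inclusive,
#'   default 0.05).
#' @param effect_threshold Gate on |effect| in NPX units (default 1).
#' @param test `"welch"` (default, Welch's t-test) or `"wilcoxon"`
#'   (rank-sum).
#' @return A tibble of class `dea_result`, one row per protein: `protein_id,
#'   effect, p_value, adj_p_value, significant, direction` ("up"/"down"),
#'   and `skipped` (fewer than 2 usable values per group, or constant in
#'   both groups — never significant).
#' @export
run_dea <- function(matrix, group_labels, p_threshold = 0.05,
                    effect_threshold = 1, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(inherits(matrix, "npx_matrix"))
  if (!is.null(names(group_labels))) {
    group_labels <- group_labels[matrix$sample_id]
  }
  if (length(group_labels) != nrow(matrix)) {
    abort_parameter("group_labels must align with the matrix samples")
  }
  f <- factor(group_labels)
  if (nlevels(f) != 2) abort_parameter("exactly two groups are required")
  lv <- levels(f)
  rows <- purrr::map(npx_proteins(matrix), function(pr) {
    v <- matrix[[pr]]
    g1 <- v[f == lv[1] & is.finite(v)]
    g2 <- v[f == lv[2] & is.finite(v)]
    if (length(g1) < 2 || length(g2) < 2) {
      return(tibble::tibble(
        protein_id = pr, effect = NA_real_, p_value = NA_real_, skipped = TRUE
      ))
    }
    effect <- mean(g2) - mean(g1)
    p <- if (stats::var(g1) == 0 && stats::var(g2) == 0) {
      NA_real_ # constant in both groups: no test is defined
    } else if (test == "welch") {
      tryCatch(stats::t.test(g2, g1)$p.value, error = function(e) NA_real_)
    } else {
      suppressWarnings(stats::wilcox.test(g2, g1, exact = FALSE)$p.value)
    }
    tibble::tibble(protein_id = pr, effect = effect, p_value = p, skipped = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$adj_p_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$adj_p_value) &
    out$adj_p_value <= p_threshold &
    !is.na(out$effect) & abs(out$effect) >= effect_threshold
  out$direction <- ifelse(is.na(out$effect), NA_character_,
    ifelse(out$effect >= 0, "up", "down")
  )
  structure(
    out[c("protein_id", "effect", "p_value", "adj_p_value",
          "significant", "direction", "skipped")],
    p_threshold = p_threshold, effect_threshold = effect_threshold,
    test = test, groups = lv,
    class = c("dea_result", class(tibble::tibble()))
  )
}

#' Scale selected proteins' NPX values
#'
#' Multiplies the NPX values of the named proteins by a positive factor,
#' emulating (mis-)application of a transformation factor; all other
#' proteins are untouched.
#'
#' @param matrix An [npx_matrix()].
#' @param factor Positive multiplier.
#' @param proteins Protein IDs to scale (default: all).
#' @return The scaled `npx_matrix`.
#' @export
scale_values <- function(matrix, factor, proteins = NULL) {
  stopifnot(inherits(matrix, "npx_matrix"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) || factor <= 0) {
    abort_parameter("factor must be a single positive number")
  }
  if (is.null(proteins)) proteins <- npx_proteins(matrix)
  unknown <- setdiff(proteins, npx_proteins(matrix))
  if (length(unknown)) {
    abort_parameter(paste0("unknown protein(s): ", paste(unknown, collapse = ", ")))
  }
  out <- tibble::as_tibble(matrix)
  for (pr in proteins) out[[pr]] <- out[[pr]] * factor
  npx_matrix(out, medium = npx_medium(matrix))
}

#' Classify findings before vs after mis-scaling
#'
#' Compares significance calls between the original and a modified DEA:
#' true positives keep significance and direction; false positives are
#' significant only in the modified analysis, or significant in both with a
#' flipped direction; false negatives lose significance. A direction-flipped
#' protein counts as both FP and FN (its original finding is not retained,
#' and the modified call is spurious), which keeps
#' retention = TP / (TP + FN) well defined.
#'
#' @param original,modified `dea_result` tables over the same proteins and
#'   thresholds.
#' @return A list with `n_tp`, `n_fp`, `n_fn` and a per-protein `detail`
#'   tibble (`protein_id, status` in \{tp, fp, fn, flip, ns\}).
#' @export
classify_tp_fp_fn <- function(original, modified) {
  o <- tibble::as_tibble(original)
  m <- tibble::as_tibble(modified)
  if (!setequal(o$protein_id, m$protein_id)) {
    abort_integrity("original and modified DEA cover different proteins")
  }
  j <- dplyr::inner_join(
    dplyr::select(o, "protein_id", sig_o = "significant", dir_o = "direction"),
    dplyr::select(m, "protein_id", sig_m = "significant", dir_m = "direction"),
    by = "protein_id"
  )
  same_dir <- j$sig_o & j$sig_m & j$dir_o == j$dir_m
  flip <- j$sig_o & j$sig_m & j$dir_o != j$dir_m
  fp_only <- !j$sig_o & j$sig_m
  fn_only <- j$sig_o & !j$sig_m
  status <- dplyr::case_when(
    same_dir ~ "tp",
    flip ~ "flip",
    fp_only ~ "fp",
    fn_only ~ "fn",
    TRUE ~ "ns"
  )
  list(
    n_tp = sum(same_dir),
    n_fp = sum(fp_only) + sum(flip),
    n_fn = sum(fn_only) + sum(flip),
    detail = tibble::tibble(protein_id = j$protein_id, status = status)
  )
}

#' Transformation-error sensitivity sweep
#'
#' Quantifies how a mis-estimated transformation factor propagates into
#' differential-expression conclusions: the original DEA is run once, then
#' for each factor on the grid all (or selected) proteins are scaled, the
#' DEA re-run, and each protein classified TP/FP/FN against the original
#' calls. A factor of exactly 1 reproduces the original analysis, so
#' FP = FN = 0 and retention = 1 there.
#'
#' @inheritParams run_dea
#' @param factors Scaling grid (default 0.6 to 1.4 by 0.1, spanning the
#'   plausible error range around a true factor of 1).
#' @param proteins Proteins to scale (default: all, emulating a uniformly
#'   wrong factor).
#' @return A tibble of class `sensitivity_sweep`, one row per factor:
#'   `factor, n_tp, n_fp, n_fn, retention` with
#'   retention = TP / (TP + FN) = fraction of original findings retained
#'   (NA when the original DEA found nothing). The original `dea_result` is
#'   attached as attribute `original`.
#' @export
sensitivity_sweep <- function(matrix, group_labels,
                              factors = seq(0.6, 1.4, by = 0.1),
                              proteins = NULL,
                              p_threshold = 0.05, effect_threshold = 1,
                              test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    abort_parameter("all factors must be positive")
  }
  factors <- sort(factors)
  original <- run_dea(matrix, group_labels,
    p_threshold = p_threshold,
    effect_threshold = effect_threshold, test = test
  )
  rows <- purrr::map(factors, function(f) {
    scaled <- scale_values(matrix, f, proteins = proteins)
    modified <- run_dea(scaled, group_labels,
      p_threshold = p_threshold,
      effect_threshold = effect_threshold, test = test
    )
    cls <- classify_tp_fp_fn(original, modified)
    tibble::tibble(
      factor = f, n_tp = cls$n_tp, n_fp = cls$n_fp, n_fn = cls$n_fn,
      retention = ifelse(cls$n_tp + cls$n_fn > 0,
        cls$n_tp / (cls$n_tp + cls$n_fn), NA_real_
      )
    )
  })
  structure(dplyr::bind_rows(rows),
    original = original,
    p_threshold = p_threshold, effect_threshold = effect_threshold,
    class = c("sensitivity_sweep", class(tibble::tibble()))
  )
}

#' Per-factor retention and false-positive rate table
#'
#' @param records A `sensitivity_sweep` table (or compatible tibble with
#'   `factor, n_tp, n_fp, n_fn` columns).
#' @return Tibble with `factor`, `retention` (TP / (TP + FN)) and
#'   `fp_fraction` (FP / (TP + FP), i.e. relative to the modified
#'   significant-set size) plus `fp_vs_original` (FP / (TP + FN)).
#' @export
retention_curve <- function(records) {
  tbl <- tibble::as_tibble(records)
  if (!nrow(tbl)) abort_parameter("no sensitivity records")
  dplyr::transmute(
    tbl,
    factor = .data$factor,
    retention = ifelse(.data$n_tp + .data$n_fn > 0,
      .data$n_tp / (.data$n_tp + .data$n_fn), NA_real_
    ),
    fp_fraction = ifelse(.data$n_tp + .data$n_fp > 0,
      .data$n_fp / (.data$n_tp + .data$n_fp), 0
    ),
    fp_vs_original = ifelse(.data$n_tp + .data$n_fn > 0,
      .data$n_fp / (.data$n_tp + .data$n_fn), NA_real_
    )
  )
}

#' Tidy a DEA result
#'
#' @param x A `dea_result`.
#' @param ... Unused.
#' @return The per-protein table as a plain tibble.
#' @method tidy dea_result
#' @export
tidy.dea_result <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a DEA result
#'
#' @param x A `dea_result`.
#' @param ... Unused.
#' @return Tibble with protein counts, significant counts by direction and
#'   the thresholds applied.
#' @method glance dea_result
#' @export
glance.dea_result <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$direction == "up"),
    n_down = sum(x$significant & x$direction == "down"),
    n_skipped = sum(x$skipped),
    p_threshold = attr(x, "p_threshold"),
    effect_threshold = attr(x, "effect_threshold")
  )
}
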