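#' Configuration for a synthetic matched serum/plasma cohort
#'
#' The generator emulates the structure of a matched-aliquot Olink study:
#' per-protein linear serum-to-plasma relationships with heterogeneous
#' slopes, heterogeneous per-protein serum variance (including a
#' near-zero-variance stratum that should fail modelling), Gaussian residual
#' noise on the log2 (NPX) scale, and a small fraction of proteins carrying
#' gross plasma-side outlier samples.
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 19 subjects, 200 proteins, slopes uniform on
#' \[0.6, 1.3\], serum means uniform on \[2, 10\] NPX, a 75/25 mix of
#' variable (SD 0.8-2.0) and low-variance (SD 0.03-0.15) proteins, residual
#' SD uniform on \[0.2, 1.5\], and 10% of proteins with 2 displaced plasma
#' points of magnitude 8 NPX.
#'
#' @param n_subjects Number of matched subjects (>= 4).
#' @param n_proteins Number of proteins.
#' @param true_slopes Optional fixed per-protein slopes; otherwise drawn
#'   uniformly from `slope_range`.
#' @param slope_range Range of the slope law.
#' @param true_intercepts Per-protein intercepts (recycled; default 0).
#' @param serum_mean_range Range of per-protein serum mean NPX.
#' @param serum_sd_range SD range of the variable stratum.
#' @param low_var_fraction Fraction of proteins in the low-variance stratum.
#' @param low_var_sd_range SD range of the low-variance stratum.
#' @param noise_sd Residual SD of plasma given serum: a single value, a
#'   per-protein vector, or a length-2 range to draw from.
#' @param outlier_fraction Fraction of proteins given gross outliers.
#' @param n_outliers Displaced samples per affected protein.
#' @param outlier_magnitude Plasma displacement magnitude in NPX units
#'   (sign drawn at random per point).
#' @param seed Integer seed; a fixed seed gives bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 19, n_proteins = 200,
                       true_slopes = NULL, slope_range = c(0.6, 1.3),
                       true_intercepts = 0,
                       serum_mean_range = c(2, 10),
                       serum_sd_range = c(0.8, 2.0),
                       low_var_fraction = 0.25,
                       low_var_sd_range = c(0.03, 0.15),
                       noise_sd = c(0.2, 1.5),
                       outlier_fraction = 0.10, n_outliers = 2,
                       outlier_magnitude = 8,
                       seed = 1L) {
  if (n_subjects < 4) abort_parameter("n_subjects must be >= 4")
  if (n_proteins < 1) abort_parameter("n_proteins must be >= 1")
  if (!is.null(true_slopes) && length(true_slopes) != n_proteins) {
    abort_parameter("true_slopes must have one value per protein")
  }
  if (any(noise_sd < 0) || any(serum_sd_range < 0) || any(low_var_sd_range < 0)) {
    abort_parameter("standard deviations must be nonnegative")
  }
  if (low_var_fraction < 0 || low_var_fraction > 1 ||
    outlier_fraction < 0 || outlier_fraction > 1) {
    abort_parameter("fractions must lie in [0, 1]")
  }
  if (n_outliers < 0 || n_outliers > n_subjects - 3) {
    abort_parameter("n_outliers must leave at least 3 clean samples")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic matched cohort with known truth
#'
#' Serum values are drawn per protein from its mean/SD law; plasma is
#' intercept + slope x serum + Gaussian noise; designated outlier samples
#' get their plasma value displaced by the configured magnitude. The truth
#' table enables recovery tests of every pipeline stage.
#'
#' @param config A [sim_config()].
#' @return A list: `cohort` (a `matched_cohort`) and `truth` (tibble with
#'   per-protein `protein_id, slope, intercept, serum_mean, serum_sd,
#'   noise_sd, low_variance, outlier_samples` (list-column of subject IDs)).
#' @export
gen_matched_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, gen_matched_cohort_impl(config, label = "synthetic"))
}

gen_matched_cohort_impl <- function(config, label, truth = NULL,
                                    n_subjects = config$n_subjects) {
  n <- n_subjects
  p <- config$n_proteins
  if (is.null(truth)) truth <- draw_truth(config)
  ids <- sprintf("S%03d", seq_len(n))
  serum <- matrix(NA_real_, n, p)
  plasma <- matrix(NA_real_, n, p)
  outliers <- vector("list", p)
  for (j in seq_len(p)) {
    s <- stats::rnorm(n, truth$serum_mean[j], truth$serum_sd[j])
    pl <- truth$intercept[j] + truth$slope[j] * s +
      stats::rnorm(n, 0, truth$noise_sd[j])
    out_j <- character(0)
    if (truth$has_outliers[j] && config$n_outliers > 0) {
      idx <- sample.int(n, config$n_outliers)
      pl[idx] <- pl[idx] +
        config$outlier_magnitude * sample(c(-1, 1), config$n_outliers, replace = TRUE)
      out_j <- ids[sort(idx)]
    }
    serum[, j] <- s
    plasma[, j] <- pl
    outliers[[j]] <- out_j
  }
  colnames(serum) <- colnames(plasma) <- truth$protein_id
  sm <- npx_matrix(
    tibble::as_tibble(cbind(tibble::tibble(sample_id = ids), tibble::as_tibble(serum))),
    medium = "serum"
  )
  pm <- npx_matrix(
    tibble::as_tibble(cbind(tibble::tibble(sample_id = ids), tibble::as_tibble(plasma))),
    medium = "plasma"
  )
  cohort <- pair_matched(sm, pm, cohort_label = label)
  truth_out <- truth
  truth_out$outlier_samples <- outliers
  list(cohort = cohort, truth = truth_out)
}

draw_truth <- function(config) {
  p <- config$n_proteins
  slope <- config$true_slopes %||%
    stats::runif(p, config$slope_range[1], config$slope_range[2])
  low <- stats::runif(p) < config$low_var_fraction
  sd <- ifelse(low,
    stats::runif(p, config$low_var_sd_range[1], config$low_var_sd_range[2]),
    stats::runif(p, config$serum_sd_range[1], config$serum_sd_range[2])
  )
  noise <- config$noise_sd
  if (length(noise) == 2 && p != 2) {
    noise <- stats::runif(p, noise[1], noise[2])
  } else {
    noise <- rep_len(noise, p)
  }
  tibble::tibble(
    protein_id = sprintf("P%04d", seq_len(p)),
    slope = slope,
    intercept = rep_len(config$true_intercepts, p),
    serum_mean = stats::runif(p, config$serum_mean_range[1], config$serum_mean_range[2]),
    serum_sd = sd,
    noise_sd = noise,
    low_variance = low,
    has_outliers = stats::runif(p) < config$outlier_fraction
  )
}

#' Generate two matched cohorts sharing the same truth
#'
#' Emulates a discovery/validation design: both cohorts use the same
#' per-protein slopes, intercepts and noise laws but independent subjects
#' (sizes `n` and `n2`) and independent noise, so cross-cohort slope
#' concordance can be studied against ground truth.
#'
#' @param config A [sim_config()] describing the first cohort.
#' @param n2 Number of subjects in the second cohort (default 40).
#' @return A list: `cohort_a`, `cohort_b` (both `matched_cohort`) and the
#'   shared `truth` (outlier assignments are per cohort: columns
#'   `outlier_samples_a`, `outlier_samples_b`).
#' @export
gen_paired_cohorts <- function(config, n2 = 40) {
  stopifnot(inherits(config, "sim_config"))
  if (n2 < 4) abort_parameter("n2 must be >= 4")
  withr::with_seed(config$seed, {
    truth <- draw_truth(config)
    a <- gen_matched_cohort_impl(config, label = "cohort_a", truth = truth)
    b <- gen_matched_cohort_impl(config,
      label = "cohort_b", truth = truth,
      n_subjects = n2
    )
    truth_out <- truth
    truth_out$outlier_samples_a <- a$truth$outlier_samples
    truth_out$outlier_samples_b <- b$truth$outlier_samples
    list(cohort_a = a$cohort, cohort_b = b$cohort, truth = truth_out)
  })
}

#' Configuration for a synthetic two-group study
#'
#' Emulates the two-group Olink comparisons used to study how factor error
#' propagates into differential expression: balanced groups, a subset of
#' proteins with a spiked log2 fold-change, Gaussian within-group noise.
#'
#' @param n_per_group Samples per group.
#' @param n_proteins Number of proteins.
#' @param n_de Number of truly differential proteins.
#' @param de_effect NPX-unit group difference for DE proteins (sign drawn at
#'   random per protein; default 1.2, comfortably past the 1-NPX fold-change
#'   gate).
#' @param within_sd Within-group SD in NPX units.
#' @param mean_range Range of baseline protein means.
#' @param seed Integer seed.
#' @return A validated list of class `two_group_config`.
#' @export
two_group_config <- function(n_per_group = 20, n_proteins = 200, n_de = 30,
                             de_effect = 1.2, within_sd = 0.3,
                             mean_range = c(2, 10), seed = 1L) {
  if (n_per_group < 2) abort_parameter("n_per_group must be >= 2")
  if (n_de > n_proteins) abort_parameter("n_de cannot exceed n_proteins")
  if (within_sd < 0) abort_parameter("within_sd must be nonnegative")
  if (de_effect < 0) abort_parameter("de_effect is a magnitude; it must be >= 0")
  structure(as.list(environment()), class = "two_group_config")
}

#' Generate a synthetic two-group study with known truth
#'
#' @param config A [two_group_config()].
#' @return A list: `matrix` (an `npx_matrix`), `labels` (named per-sample
#'   group labels, "A"/"B") and `truth` (tibble with `protein_id, is_de,
#'   effect` where effect is the signed B-minus-A mean difference).
#' @export
gen_two_group_study <- function(config) {
  stopifnot(inherits(config, "two_group_config"))
  withr::with_seed(config$seed, {
    n <- 2 * config$n_per_group
    p <- config$n_proteins
    ids <- sprintf("G%03d", seq_len(n))
    labels <- stats::setNames(rep(c("A", "B"), each = config$n_per_group), ids)
    is_de <- c(
      rep(TRUE, config$n_de),
      rep(FALSE, p - config$n_de)
    )[sample.int(p)]
    effect <- ifelse(is_de,
      config$de_effect * sample(c(-1, 1), p, replace = TRUE), 0
    )
    base <- stats::runif(p, config$mean_range[1], config$mean_range[2])
    vals <- matrix(stats::rnorm(n * p, 0, config$within_sd), n, p)
    vals <- sweep(vals, 2, base, "+")
    in_b <- labels == "B"
    vals[in_b, ] <- sweep(vals[in_b, , drop = FALSE], 2, effect, "+")
    colnames(vals) <- sprintf("P%04d", seq_len(p))
    m <- npx_matrix(
      tibble::as_tibble(cbind(tibble::tibble(sample_id = ids), tibble::as_tibble(vals))),
      medium = "plasma"
    )
    list(
      matrix = m, labels = labels,
      truth = tibble::tibble(
        protein_id = colnames(vals), is_de = is_de, effect = effect
      )
    )
  })
}
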