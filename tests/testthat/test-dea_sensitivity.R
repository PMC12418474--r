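test_that("DEA: null data yields ~no findings, strong spikes are found", {
  null <- gen_two_group_study(two_group_config(n_proteins = 120, n_de = 0, seed = 19))
  res <- run_dea(null$matrix, null$labels)
  expect_lte(sum(res$significant), 1) # BH-adjusted null

  # one protein with a +2 NPX group shift and tiny noise: certain detection
  spiked <- gen_two_group_study(two_group_config(
    n_per_group = 10, n_proteins = 20, n_de = 0, within_sd = 0.1, seed = 29
  ))
  m <- spiked$matrix
  m$P0001[spiked$labels[m$sample_id] == "B"] <-
    m$P0001[spiked$labels[m$sample_id] == "B"] + 2
  res <- run_dea(m, spiked$labels)
  hit <- res[res$protein_id == "P0001", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "up")
  expect_equal(hit$effect, 2, tolerance = 0.2)
})

test_that("the effect gate blocks sub-threshold fold-changes regardless of p", {
  sim <- gen_two_group_study(two_group_config(
    n_per_group = 15, n_proteins = 10, n_de = 0, within_sd = 0.05, seed = 31
  ))
  m <- sim$matrix
  in_b <- sim$labels[m$sample_id] == "B"
  m$P0002[in_b] <- m$P0002[in_b] + 0.5 # fold-change < 2 but tiny p
  res <- run_dea(m, sim$labels)
  row <- res[res$protein_id == "P0002", ]
  expect_lt(row$adj_p_value, 1e-6)
  expect_false(row$significant)
})

test_that("constant or under-sampled proteins are skipped, never significant", {
  m <- npx_matrix(tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    FLAT = rep(2, 8),
    OK = c(1, 2, 1.5, 1.8, 5, 6, 5.5, 5.8)
  ))
  labels <- stats::setNames(rep(c("A", "B"), each = 4), m$sample_id)
  res <- run_dea(m, labels)
  flat <- res[res$protein_id == "FLAT", ]
  expect_true(is.na(flat$p_value))
  expect_false(flat$significant)

  m2 <- m
  m2$OK[1:3] <- NA # one usable A sample left
  res2 <- run_dea(m2, labels)
  expect_true(res2$skipped[res2$protein_id == "OK"])
  expect_false(res2$significant[res2$protein_id == "OK"])
})

test_that("scale_values multiplies selected proteins and inverts exactly", {
  sim <- gen_two_group_study(two_group_config(n_proteins = 10, n_de = 2, seed = 3))
  m <- sim$matrix
  s1 <- scale_values(m, 1.0)
  expect_equal(tibble::as_tibble(s1), tibble::as_tibble(m))
  s06 <- scale_values(m, 0.6, proteins = "P0001")
  expect_equal(s06$P0001, m$P0001 * 0.6)
  expect_equal(s06$P0002, m$P0002)
  back <- scale_values(scale_values(m, 1.4), 1 / 1.4)
  for (pr in npx_proteins(m)) expect_equal(back[[pr]], m[[pr]], tolerance = 1e-12)
  expect_error(scale_values(m, 0), class = "npx_parameter_error")
  expect_error(scale_values(m, -1), class = "npx_parameter_error")
  expect_error(scale_values(m, 1, proteins = "NOPE"), class = "npx_parameter_error")
})

test_that("TP/FP/FN classification follows the retention accounting", {
  mk <- function(sig, dir) {
    structure(
      tibble::tibble(
        protein_id = paste0("P", seq_along(sig)),
        effect = ifelse(dir == "up", 2, -2),
        p_value = 0.001, adj_p_value = 0.001,
        significant = sig, direction = dir, skipped = FALSE
      ),
      class = c("dea_result", class(tibble::tibble()))
    )
  }
  orig <- mk(c(TRUE, TRUE, FALSE, TRUE), c("up", "down", "up", "up"))

  same <- classify_tp_fp_fn(orig, orig)
  expect_equal(same$n_tp, 3)
  expect_equal(same$n_fp, 0)
  expect_equal(same$n_fn, 0)

  # one protein significant only in the modified list
  mod <- mk(c(TRUE, TRUE, TRUE, TRUE), c("up", "down", "up", "up"))
  cls <- classify_tp_fp_fn(orig, mod)
  expect_equal(cls$n_fp, 1)
  expect_equal(cls$n_fn, 0)

  # direction flip counts as both FP and FN, never TP
  flip <- mk(c(TRUE, TRUE, FALSE, TRUE), c("down", "down", "up", "up"))
  cls2 <- classify_tp_fp_fn(orig, flip)
  expect_equal(cls2$n_tp, 2)
  expect_equal(cls2$n_fp, 1)
  expect_equal(cls2$n_fn, 1)
  expect_equal(cls2$detail$status[1], "flip")

  # conservation: TP + FN = originally significant, in every comparison
  for (cls_i in list(same, cls, cls2)) {
    expect_equal(cls_i$n_tp + cls_i$n_fn, sum(orig$significant))
  }

  bad <- mk(TRUE, "up")
  expect_error(classify_tp_fp_fn(orig, bad), class = "npx_integrity_error")
})

test_that("sweep: exact identity at factor 1, conservation across the grid", {
  sim <- gen_two_group_study(two_group_config(
    n_proteins = 120, n_de = 25, seed = 47
  ))
  sw <- sensitivity_sweep(sim$matrix, sim$labels)
  expect_equal(sw$factor, seq(0.6, 1.4, by = 0.1))
  at1 <- sw[abs(sw$factor - 1) < 1e-9, ]
  expect_equal(at1$n_fp, 0L)
  expect_equal(at1$n_fn, 0L)
  expect_equal(at1$retention, 1)
  n_orig <- sum(attr(sw, "original")$significant)
  expect_gt(n_orig, 0)
  expect_true(all(sw$n_tp + sw$n_fn == n_orig))
})

test_that("retention decays monotonically for effects near the gate", {
  # all true effects just above the 1-NPX gate: any shrinkage of |effect|
  # pushes findings below it, so retention is non-increasing in |factor - 1|
  sim <- gen_two_group_study(two_group_config(
    n_proteins = 200, n_de = 30, de_effect = 1.12, within_sd = 0.15, seed = 53
  ))
  sw <- sensitivity_sweep(sim$matrix, sim$labels)
  below <- sw[sw$factor <= 1, ]
  expect_true(all(diff(below$retention) >= 0)) # rising back toward 1
  curve <- retention_curve(sw)
  expect_equal(
    max(curve$retention, na.rm = TRUE),
    curve$retention[which.min(abs(curve$factor - 1))]
  )
})

test_that("scaling a protein far from both gates changes no counts", {
  sim <- gen_two_group_study(two_group_config(
    n_proteins = 50, n_de = 10, de_effect = 2.5, within_sd = 0.1, seed = 59
  ))
  null_protein <- sim$truth$protein_id[!sim$truth$is_de][1]
  sw <- sensitivity_sweep(sim$matrix, sim$labels,
    factors = c(0.9, 1, 1.1), proteins = null_protein
  )
  expect_true(all(sw$n_fp == 0))
  expect_true(all(sw$n_fn == 0))
  expect_true(all(sw$retention == 1))
})

test_that("retention_curve arithmetic and denominators", {
  rec <- tibble::tibble(factor = c(1, 1.2), n_tp = c(4L, 3L), n_fp = c(0L, 1L), n_fn = c(0L, 1L))
  curve <- retention_curve(rec)
  expect_equal(curve$retention, c(1, 0.75))
  expect_equal(curve$fp_fraction, c(0, 0.25))
  expect_equal(curve$fp_vs_original, c(0, 0.25))
  expect_error(retention_curve(rec[0, ]), class = "npx_parameter_error")
})
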