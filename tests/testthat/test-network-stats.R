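# Edgewise group statistics, NBS permutation FWE, edge-behavior correlation.

make_z <- function(n, E, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * E), n, E,
         dimnames = list(sprintf("S%03d", 1:n), paste0("e", 1:E)))
}

small_design <- function(n_per_cell) {
  generate_design(n_per_cell)
}

test_that("edgewise stats flag all-identical matrices as degenerate, not as signal", {
  design <- small_design(2)
  z <- matrix(rep(c(0.5, 0.2, 0.9), each = 8), 8, 3,
              dimnames = list(design$subject_id, c("a", "b", "c")))
  res <- edgewise_group_stats(z, design)
  expect_true(all(res$degenerate))
  expect_true(all(res$p_exposure == 1))
  expect_true(all(res$F_exposure == 0))
})

test_that("sex statistics are orthogonal to the exposure labeling", {
  design <- small_design(5)
  set.seed(31)
  z <- make_z(20, 6, seed = 31)
  res1 <- edgewise_group_stats(z, design)
  # flipping the exposure level labels flips t but leaves every ANOVA
  # statistic identical
  flipped <- design
  flipped$exposure <- ifelse(design$exposure == "AIE", "Wat", "AIE")
  res2 <- edgewise_group_stats(z, flipped)
  expect_equal(res1$F_sex, res2$F_sex, tolerance = 1e-10)
  expect_equal(res1$F_exposure, res2$F_exposure, tolerance = 1e-10)
  expect_equal(res1$t_signed, -res2$t_signed, tolerance = 1e-10)
  # the marginal sex contrast does not involve exposure labels at all
  shuffled <- design
  shuffled$exposure <- sample(design$exposure)
  sex_t_1 <- vapply(seq_len(ncol(z)), function(e) {
    oracle_pooled_t(z[design$sex == "F", e], z[design$sex == "M", e])
  }, numeric(1))
  sex_t_2 <- vapply(seq_len(ncol(z)), function(e) {
    oracle_pooled_t(z[shuffled$sex == "F", e], z[shuffled$sex == "M", e])
  }, numeric(1))
  expect_equal(sex_t_1, sex_t_2, tolerance = 1e-12)
})

test_that("the planted edge attains the maximum |t| with high probability", {
  hits <- vapply(1:20, function(s) {
    eff <- planted_network_effect(affected_edges = "NAc-CPu", delta = 0.3,
                                  subject_sd = 0, edge_sd = 0)
    design <- generate_design(5)
    ts <- generate_roi_timeseries(design, eff, n_timepoints = 500, seed = s)
    z <- edge_matrix(lapply(ts, connectivity_matrix))
    stats <- edgewise_group_stats(z, design)
    stats$edge[which.max(stats$t_value)] == "NAc-CPu"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("exhaustive link-based NBS equals the brute-force enumeration exactly", {
  # 3 ROIs -> 3 edges, 4 vs 4 subjects -> 70 assignments
  set.seed(77)
  design <- tibble::tibble(subject_id = sprintf("S%d", 1:8),
                           exposure = rep(c("AIE", "Wat"), each = 4))
  z <- matrix(rnorm(24), 8, 3,
              dimnames = list(design$subject_id,
                              c("PrL-NAc", "PrL-CPu", "NAc-CPu")))
  res <- nbs_fwe(z, design$exposure, n_perm = 5000, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 70L)
  oracle <- oracle_nbs_link(z, as.numeric(design$exposure == "AIE"))
  expect_identical(unname(res$table$corrected_p), unname(oracle))
  expect_true(all(res$table$corrected_p >= res$table$p_uncorrected - 1e-12))
})

test_that("NBS is deterministic given a seed and monotone in |t|", {
  set.seed(41)
  z <- make_z(20, 10, seed = 41)
  labels <- rep(c("AIE", "Wat"), each = 10)
  r1 <- nbs_fwe(z, labels, n_perm = 400, seed = 9)
  r2 <- nbs_fwe(z, labels, n_perm = 400, seed = 9)
  expect_identical(r1$table, r2$table)
  ord <- order(abs(r1$table$t_signed))
  expect_true(all(diff(r1$table$corrected_p[ord]) <= 1e-12))
  # corrected p lives on the k/n_perm grid
  expect_true(all(abs(r1$table$corrected_p * r1$n_perm -
                        round(r1$table$corrected_p * r1$n_perm)) < 1e-9))
  expect_error(nbs_fwe(z[1:3, ], rep(c("AIE", "Wat"), c(1, 2)), n_perm = 100),
               class = "flexconn_validation_error")
})

test_that("component NBS finds the planted component and none under a tight threshold", {
  cfg_eff <- planted_network_effect()
  design <- generate_design(8)
  ts <- generate_roi_timeseries(design, cfg_eff, n_timepoints = 400, seed = 3)
  z <- edge_matrix(lapply(ts, connectivity_matrix))
  res <- nbs_fwe(z, design$exposure, n_perm = 300, seed = 2,
                 variant = "component", edges = edge_table(default_rois()))
  expect_s3_class(res$components, "tbl_df")
  sig <- res$table$edge[res$table$significant]
  expect_true(any(cfg_eff$affected_edges %in% sig))
  # near-zero suprathreshold probability: no components on null data
  znull <- make_z(20, 28, seed = 55)
  colnames(znull) <- edge_table(default_rois())$edge
  res0 <- nbs_fwe(znull, rep(c("AIE", "Wat"), each = 10), supra_p = 1e-6,
                  n_perm = 200, seed = 2, variant = "component",
                  edges = edge_table(default_rois()))
  expect_equal(nrow(res0$components), 0L)
})

test_that("edge-behavior correlation recovers exact and planted associations", {
  set.seed(61)
  design <- small_design(5)
  z <- make_z(20, 5, seed = 61)
  behavior <- z[, 3]
  res <- edge_behavior_correlation(z, behavior, design)
  expect_equal(res$r_behavior[3], 1)
  expect_equal(which.min(res$p_beta), 3L)
  expect_true(all(res$q_fdr >= res$p_beta - 1e-12))
  # planted negative association keeps the sign convention
  set.seed(62)
  beh2 <- -z[, 2] + rnorm(20, sd = 0.5)
  res2 <- edge_behavior_correlation(z, beh2, design)
  expect_lt(res2$r_behavior[2], 0)
  expect_error(edge_behavior_correlation(z, rep(1, 20)),
               class = "flexconn_degenerate_error")
})

test_that("null edge-behavior FDR discoveries stay at the nominal rate", {
  set.seed(63)
  n_rep <- 300
  frac <- vapply(seq_len(n_rep), function(i) {
    z <- matrix(rnorm(20 * 28), 20, 28)
    behavior <- rnorm(20)
    mean(edge_behavior_correlation(z, behavior)$q_fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 2 * sd(frac) / sqrt(n_rep) + 0.01)
})
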