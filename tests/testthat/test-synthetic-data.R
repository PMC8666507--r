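# Generators: design, ROI time series with planted effects, counts, trial
# sequences, event logs. Determinism and planted-truth recoverability.

test_that("generate_design produces exact balanced cells, deterministically", {
  d <- generate_design(10)
  expect_equal(nrow(d), 40L)
  expect_true(all(table(d$sex, d$exposure) == 10))
  expect_false(anyDuplicated(d$subject_id) > 0)
  expect_identical(generate_design(10, seed = 3), generate_design(10, seed = 3))
  expect_error(generate_design(0), class = "flexconn_validation_error")
})

test_that("reduced_corr subtracts delta on affected edges and repairs PD", {
  eff <- planted_network_effect(delta = 0.3)
  red <- reduced_corr(eff)
  expect_equal(red["NAc", "CPu"], 0.05, tolerance = 0.02)
  expect_equal(red["PrL", "IL"], 0.35, tolerance = 0.02)
  expect_gt(min(eigen(red, symmetric = TRUE)$values), 0)
  expect_equal(unname(diag(unclass(red))), rep(1, 8))
  # an indefinite base matrix is rejected with the offending eigenvalue
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(
    planted_network_effect(base_corr = bad, roi_names = c("A", "B", "C"),
                           affected_edges = "A-B"),
    "eigenvalue", class = "flexconn_validation_error"
  )
})

test_that("null network effect (delta = 0) leaves group mean correlations equal", {
  eff <- planted_network_effect(delta = 0, subject_sd = 0, edge_sd = 0)
  design <- generate_design(50)
  ts <- generate_roi_timeseries(design, eff, n_timepoints = 150, seed = 8)
  conn <- lapply(ts, connectivity_matrix)
  r <- edge_matrix(conn, "r")
  aie <- design$exposure == "AIE"
  diff <- colMeans(r[aie, ]) - colMeans(r[!aie, ])
  mc_se <- sqrt(2 / 100) / sqrt(150 - 3)  # two groups of 100, var(r) ~ 1/(T-3)
  expect_true(all(abs(diff) < 4 * mc_se))
})

test_that("a planted delta on one edge shifts that edge's mean r by about delta", {
  eff <- planted_network_effect(affected_edges = "NAc-CPu", delta = 0.3,
                                subject_sd = 0, edge_sd = 0)
  design <- generate_design(15)
  ts <- generate_roi_timeseries(design, eff, n_timepoints = 2000, seed = 9)
  r <- edge_matrix(lapply(ts, connectivity_matrix), "r")
  aie <- design$exposure == "AIE"
  gap <- mean(r[!aie, "NAc-CPu"]) - mean(r[aie, "NAc-CPu"])
  expect_equal(gap, 0.3, tolerance = 0.05)
  other <- mean(r[!aie, "PrL-IL"]) - mean(r[aie, "PrL-IL"])
  expect_lt(abs(other), 0.05)
})

test_that("time-series generation is deterministic and counter-seeded per subject", {
  eff <- planted_network_effect()
  d <- generate_design(2)
  t1 <- generate_roi_timeseries(d, eff, n_timepoints = 60, seed = 5)
  t2 <- generate_roi_timeseries(d, eff, n_timepoints = 60, seed = 5)
  expect_identical(t1[["S001"]]$data, t2[["S001"]]$data)
  # removing later subjects does not change earlier subjects' draws
  d_small <- d[1:4, ]
  t3 <- generate_roi_timeseries(d_small, eff, n_timepoints = 60, seed = 5)
  expect_identical(t1[["S003"]]$data, t3[["S003"]]$data)
  expect_error(generate_roi_timeseries(d, eff, n_timepoints = 4, seed = 1),
               class = "flexconn_validation_error")
})

test_that("set-shift counts follow the planted Poisson log-linear model", {
  params <- planted_mediation(b0 = log(5), b1 = 0, b2 = 0, b3 = 0)
  design <- generate_design(125)  # n = 500
  counts <- generate_setshift_counts(design, rep(0, 500), params, seed = 2)
  expect_lt(abs(mean(counts$count) - 5), 3 * sqrt(5 / 500))
  # b1 = b2 = 0: group means equal within Monte Carlo error
  aie <- design$exposure == "AIE"
  gap <- mean(counts$count[aie]) - mean(counts$count[!aie])
  expect_lt(abs(gap), 4 * sqrt(5 / 250 * 2))
  expect_true(all(counts$count >= 0))
  big <- planted_mediation(b0 = log(10), b2 = 50)
  expect_error(generate_setshift_counts(design, rep(1, 500), big, seed = 2),
               class = "flexconn_overflow_error")
})

test_that("trial-sequence generator respects degenerate probabilities and the cap", {
  s <- generate_trial_sequence(1, 1, criterion_k = 6, seed = 1)
  expect_identical(s$outcomes, rep("correct", 6))
  expect_true(s$criterion_reached)
  s0 <- generate_trial_sequence(0, 0.9, criterion_k = 6, seed = 1,
                                max_trials = 50)
  expect_false(s0$criterion_reached)
  expect_equal(length(s0$outcomes), 50L)
  expect_true(all(s0$outcomes == "error"))
  expect_error(generate_trial_sequence(0.5, 0.5, criterion_k = 0, seed = 1),
               class = "flexconn_validation_error")
})

test_that("pre-criterion errors follow the geometric law", {
  p_pre <- 0.4
  set.seed(0)
  prepotent <- vapply(1:1000, function(i) {
    s <- generate_trial_sequence(p_pre, 0.9, criterion_k = 3, seed = i)
    classify_errors(s$outcomes)$prepotent
  }, integer(1))
  expected <- (1 - p_pre) / p_pre
  se <- sqrt((1 - p_pre) / p_pre^2 / 1000)
  expect_lt(abs(mean(prepotent) - expected), 3.5 * se)
})

test_that("event-log generator obeys rates, determinism and the empty case", {
  d <- generate_design(1)
  empty <- generate_pavlovian_eventlog(d, 0, 0, 0, n_trials = 3,
                                       n_sessions = 1, seed = 4)
  expect_true(all(empty$event_type %in%
                    c("cs_onset", "cs_offset", "sucrose_delivery")))
  m <- score_eventlog(empty[empty$subject_id == "S001" & empty$session == 1, ])
  expect_equal(m$lever_presses, 0)
  expect_equal(m$lever_latency_s, 30)

  log1 <- generate_pavlovian_eventlog(d, press_rate_cs = 0.2,
                                      entry_rate_cs = 0, entry_rate_baseline = 0,
                                      n_trials = 15, n_sessions = 10, seed = 4)
  presses <- sum(log1$event_type == "lever_press")
  n_windows <- 4 * 15 * 10
  expect_lt(abs(presses / n_windows - 6), 3 * sqrt(6 / n_windows))

  log2 <- generate_pavlovian_eventlog(d, press_rate_cs = 0.2,
                                      entry_rate_cs = 0, entry_rate_baseline = 0,
                                      n_trials = 15, n_sessions = 10, seed = 4)
  expect_identical(log1, log2)
  expect_error(generate_pavlovian_eventlog(d, press_rate_cs = -1),
               class = "flexconn_validation_error")
})

test_that("simulate_study closes the loop: mediator is the measured planted-subnetwork mean z", {
  cfg <- synthetic_config(n_per_cell = 4, n_timepoints = 120, seed = 6)
  sim <- simulate_study(cfg)
  z <- edge_matrix(sim$conn, "z")
  expect_equal(unname(sim$mediator),
               unname(rowMeans(z[, cfg$network$affected_edges])))
  expect_equal(names(sim$timeseries), sim$design$subject_id)
  # identical config => identical dataset
  sim2 <- simulate_study(synthetic_config(n_per_cell = 4, n_timepoints = 120,
                                          seed = 6))
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$timeseries[["S005"]]$data, sim2$timeseries[["S005"]]$data)
})
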