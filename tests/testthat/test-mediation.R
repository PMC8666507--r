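# Edge selection, PC1 subnetwork, counterfactual mediation.

fake_stats <- function(p_exposure) {
  tibble::tibble(
    edge = paste0("e", seq_along(p_exposure)),
    p_exposure = p_exposure,
    p_sex = runif(length(p_exposure)),
    p_interaction = runif(length(p_exposure)),
    p_t = p_exposure
  )
}

test_that("edge selection respects thresholds, order and monotonicity", {
  set.seed(71)
  p <- runif(28)
  stats <- fake_stats(p)
  expect_equal(select_edges(stats, 1.0), stats$edge)
  pmin_idx <- which.min(p)
  just_above <- sort(p)[1] + (sort(p)[2] - sort(p)[1]) / 2
  expect_equal(select_edges(stats, just_above), stats$edge[pmin_idx])
  for (i in 1:20) {
    t1 <- runif(1); t2 <- runif(1)
    lo <- min(t1, t2); hi <- max(t1, t2)
    expect_true(all(select_edges(stats, lo) %in% select_edges(stats, hi)))
  }
  expect_error(select_edges(stats, 0.1, effect = "banana"))
})

test_that("subnetwork PC1 matches a brute-force eigendecomposition", {
  set.seed(72)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("e", 1:6)))
  pc <- subnetwork_pc1(X)
  S <- cov(X)
  eig <- eigen(S, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  if (mean(v1) < 0) v1 <- -v1
  expect_equal(unname(pc$weights), v1, tolerance = 1e-10)
  expect_equal(pc$variance_explained, eig$values[1] / sum(eig$values),
               tolerance = 1e-10)
  expect_equal(sum(pc$weights^2), 1, tolerance = 1e-12)
  expect_gte(mean(pc$weights), 0)
  # scores are the centered projection
  expect_equal(unname(pc$scores),
               as.vector(scale(X, scale = FALSE) %*% v1), tolerance = 1e-10)
})

test_that("duplicated edge columns give variance_explained 1 and equal loadings", {
  set.seed(73)
  a <- rnorm(20)
  X <- cbind(e1 = a, e2 = a)
  pc <- subnetwork_pc1(X)
  expect_equal(pc$variance_explained, 1, tolerance = 1e-12)
  expect_equal(unname(pc$weights[1]), unname(pc$weights[2]), tolerance = 1e-12)
})

test_that("independent equal-variance edges approach variance_explained 1/k", {
  set.seed(74)
  k <- 4
  X <- matrix(rnorm(20000 * k), 20000, k)
  pc <- subnetwork_pc1(X)
  expect_lt(abs(pc$variance_explained - 1 / k), 0.02)
})

test_that("PC1 scores are invariant (up to sign convention) to edge reordering", {
  set.seed(75)
  X <- matrix(rnorm(25 * 5), 25, 5, dimnames = list(NULL, paste0("e", 1:5)))
  pc1 <- subnetwork_pc1(X)
  perm <- c(4, 2, 5, 1, 3)
  pc2 <- subnetwork_pc1(X[, perm])
  expect_equal(abs(pc1$scores), abs(pc2$scores), tolerance = 1e-10)
  expect_error(subnetwork_pc1(X[, 1, drop = FALSE]),
               class = "flexconn_validation_error")
  expect_error(subnetwork_pc1(cbind(e1 = rep(1, 10), e2 = rnorm(10))),
               class = "flexconn_degenerate_error")
})

sim_med_data <- function(n, a1, b1, b2, b3 = 0, sigma_m = 1, b0 = log(10),
                         seed = 1) {
  set.seed(seed)
  x <- rep(0:1, each = n / 2)
  c_ <- rep(rep(0:1, each = n / 4), 2)
  m <- a1 * x + rnorm(n, 0, sigma_m)
  y <- rpois(n, exp(b0 + b1 * x + b2 * m + b3 * c_))
  list(x = x, m = m, y = y, c = c_)
}

test_that("null mediator slope gives a unit indirect effect and zero proportion mediated", {
  d <- sim_med_data(80, a1 = 0.5, b1 = 0.3, b2 = 0, seed = 81)
  # refit with b2 forced by construction: estimate will be near 0, but the
  # algebraic identity is checked on the closed form itself
  res <- suppressWarnings(
    causal_mediation(d$x, d$m, d$y, d$c, n_boot = 200, seed = 1))
  b2_hat <- res$b_path$estimate[res$b_path$term == "m"]
  a1_hat <- res$a_path$coefficients[["x"]]
  expect_equal(log(res$rr_nie), a1_hat * b2_hat, tolerance = 1e-12)
  expect_equal(log(res$rr_nde),
               res$b_path$estimate[res$b_path$term == "x"], tolerance = 1e-12)
})

test_that("the worked algebraic case gives pm_log = 2/3 and the product decomposition holds", {
  eff <- flexconn:::med_effects_closed_form(
    a0 = 0, a1 = 0.5, a2 = 0, b1 = 0.1, b2 = 0.4, b4 = 0,
    sigma_m = 1, cbar = 0.5, include_interaction = FALSE)
  expect_equal(eff$rr_nie, exp(0.2), tolerance = 1e-14)
  expect_equal(eff$rr_nde, exp(0.1), tolerance = 1e-14)
  expect_equal(eff$pm_log, 2 / 3, tolerance = 1e-14)
  expect_equal(eff$rr_total, eff$rr_nde * eff$rr_nie, tolerance = 1e-14)
  # b2 = 0: no indirect path
  eff0 <- flexconn:::med_effects_closed_form(
    a0 = 0, a1 = 0.5, a2 = 0, b1 = 0.1, b2 = 0, b4 = 0,
    sigma_m = 1, cbar = 0.5, include_interaction = FALSE)
  expect_equal(eff0$rr_nie, 1)
  expect_equal(eff0$pm_log, 0)
  expect_equal(eff0$pm_excess_rr, 0)
})

test_that("closed-form effects match a Monte-Carlo counterfactual oracle", {
  d <- sim_med_data(200, a1 = 0.5, b1 = 0.2, b2 = 0.4, b3 = 0.1, seed = 82)
  res <- causal_mediation(d$x, d$m, d$y, d$c, n_boot = 200, seed = 2)
  a <- res$a_path$coefficients
  sm <- res$a_path$sigma_m
  b <- setNames(res$b_path$estimate, res$b_path$term)
  set.seed(9)
  n_mc <- 2e5
  cbar <- mean(d$c)
  rate <- function(x, m) exp(b[["intercept"]] + b[["x"]] * x + b[["m"]] * m +
                               b[["covariate"]] * cbar)
  draw_m <- function(x) a[["intercept"]] + a[["x"]] * x + a[["covariate"]] * cbar +
    rnorm(n_mc, 0, sm)
  m1 <- draw_m(1); m0 <- draw_m(0)
  nie_mc <- mean(rate(1, m1)) / mean(rate(1, m0))
  nde_mc <- mean(rate(1, m0)) / mean(rate(0, m0))
  mc_se <- sd(rate(1, m1)) / mean(rate(1, m1)) / sqrt(n_mc) * 4
  expect_equal(res$rr_nie, nie_mc, tolerance = 3 * mc_se)
  expect_equal(res$rr_nde, nde_mc, tolerance = 3 * mc_se)
})

test_that("mediator rescaling leaves the indirect effect and proportions unchanged", {
  d <- sim_med_data(120, a1 = 0.4, b1 = 0.2, b2 = 0.5, seed = 83)
  r1 <- causal_mediation(d$x, d$m, d$y, d$c, n_boot = 200, seed = 3)
  r2 <- causal_mediation(d$x, d$m * 7, d$y, d$c, n_boot = 200, seed = 3)
  expect_equal(r1$rr_nie, r2$rr_nie, tolerance = 1e-6)
  expect_equal(r1$rr_nde, r2$rr_nde, tolerance = 1e-6)
  expect_equal(r1$pm_log, r2$pm_log, tolerance = 1e-6)
})

test_that("interaction-model natural effects match the Monte-Carlo oracle", {
  set.seed(84)
  n <- 400
  x <- rep(0:1, each = n / 2)
  c_ <- rep(rep(0:1, each = n / 4), 2)
  m <- 0.3 + 0.5 * x + 0.2 * c_ + rnorm(n, 0, 0.8)
  y <- rpois(n, exp(1.5 + 0.2 * x + 0.3 * m + 0.25 * x * m + 0.1 * c_))
  res <- causal_mediation(x, m, y, c_, include_interaction = TRUE,
                          n_boot = 200, seed = 4)
  a <- res$a_path$coefficients; sm <- res$a_path$sigma_m
  b <- setNames(res$b_path$estimate, res$b_path$term)
  cbar <- mean(c_)
  set.seed(10)
  n_mc <- 4e5
  rate <- function(xv, mv) exp(b[["intercept"]] + b[["x"]] * xv + b[["m"]] * mv +
                                 b[["x:m"]] * xv * mv + b[["covariate"]] * cbar)
  draw_m <- function(xv) a[["intercept"]] + a[["x"]] * xv +
    a[["covariate"]] * cbar + rnorm(n_mc, 0, sm)
  m1 <- draw_m(1); m0 <- draw_m(0)
  nie_mc <- mean(rate(1, m1)) / mean(rate(1, m0))
  nde_mc <- mean(rate(1, m0)) / mean(rate(0, m0))
  expect_equal(res$rr_nie, nie_mc, tolerance = 0.02)
  expect_equal(res$rr_nde, nde_mc, tolerance = 0.02)
})

test_that("bootstrap p-values for a null indirect effect are calibrated", {
  set.seed(85)
  n_rep <- 150
  pvals <- vapply(seq_len(n_rep), function(i) {
    d <- sim_med_data(60, a1 = 0.5, b1 = 0.2, b2 = 0, seed = 9000 + i)
    suppressWarnings(
      causal_mediation(d$x, d$m, d$y, d$c, n_boot = 200, seed = i)$p_indirect
    )
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_rep) + 0.02)
})

test_that("inconsistent mediation is flagged, never silently reported", {
  d <- sim_med_data(160, a1 = 0.8, b1 = -0.5, b2 = 0.6, seed = 86)
  expect_warning(
    res <- causal_mediation(d$x, d$m, d$y, d$c, n_boot = 200, seed = 5),
    class = "flexconn_inconsistent_mediation"
  )
  expect_true(res$inconsistent)
})

test_that("recover_planted_mediation reports recovery against planted truth", {
  cfg <- synthetic_config(n_per_cell = 10, n_timepoints = 300, seed = 17)
  rec <- recover_planted_mediation(cfg, n_boot = 300, seed = 17)
  expect_gte(rec$edge_recovery, 0.6)
  med <- rec$estimates
  # signs of the planted paths are recovered
  expect_lt(med$a_path$coefficients[["x"]], 0)   # exposure lowers connectivity
  expect_lt(med$b_path$estimate[med$b_path$term == "m"], 0)
  expect_gt(med$rr_nie, 1)                       # indirect effect raises errors
})
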