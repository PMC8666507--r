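# PCA subnetwork mediator construction and counterfactual causal mediation
# with a normal mediator and Poisson (log-link) count outcome.

#' Select exposure-affected edges at an uncorrected threshold
#'
#' Returns the edges whose uncorrected p-value for the named effect falls
#' below the threshold, in the order they appear in the stats table
#' (canonical edge order). A lenient threshold (default 0.1) admits edges
#' whose weaker univariate associations can still carry shared variance into
#' the subnetwork component.
#'
#' @param stats An `edge_stats` tibble from [edgewise_group_stats()].
#' @param p_threshold Threshold in (0, 1\] (default 0.1).
#' @param effect Effect whose p-value is thresholded: `"exposure"` (default),
#'   `"sex"`, `"interaction"`, or `"exposure_t"` (the pooled two-sample t).
#' @return Character vector of selected edge labels.
#' @export
select_edges <- function(stats, p_threshold = 0.1,
                         effect = c("exposure", "sex", "interaction",
                                    "exposure_t")) {
  if (!is.character(effect)) {
    stop_flexconn("`effect` must be an effect name.", class = "flexconn_validation_error")
  }
  effect <- match.arg(effect)
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop_flexconn("`p_threshold` must lie in (0, 1].",
                  class = "flexconn_validation_error")
  }
  col <- switch(effect,
                exposure = "p_exposure", sex = "p_sex",
                interaction = "p_interaction", exposure_t = "p_t")
  if (!col %in% names(stats)) {
    stop_flexconn(sprintf("Stats table lacks column `%s`.", col))
  }
  stats$edge[stats[[col]] < p_threshold]
}

#' First-principal-component subnetwork from selected edges
#'
#' Column-centers the subjects x selected-edges Fisher-z matrix (no per-edge
#' standardization: the columns share the Fisher-z scale) and takes the first
#' right singular vector. Loadings are sign-oriented so their mean is
#' non-negative, consistent with reading the component as a cohesive
#' subnetwork; subject scores are the centered data projected onto the
#' loadings, and `variance_explained` is the first squared singular value
#' over the sum of all squared singular values.
#'
#' @param z_edges Subjects x edges numeric matrix (>= 3 subjects, >= 2
#'   edges).
#' @param scale. Standardize columns first? Default `FALSE`.
#' @return Object of class `subnetwork_component`: list with `edges`,
#'   `weights` (unit norm), `scores`, `variance_explained`,
#'   `more_edges_than_subjects` flag.
#' @export
subnetwork_pc1 <- function(z_edges, scale. = FALSE) {
  z_edges <- as.matrix(z_edges)
  if (nrow(z_edges) < 3) {
    stop_flexconn("At least 3 subjects are required.",
                  class = "flexconn_validation_error")
  }
  if (ncol(z_edges) < 2) {
    stop_flexconn("At least 2 edges are required.",
                  class = "flexconn_validation_error")
  }
  sds <- apply(z_edges, 2, stats::sd)
  if (any(sds == 0)) {
    stop_flexconn(sprintf("Constant edge column(s): %s.",
                          paste(colnames(z_edges)[sds == 0], collapse = ", ")),
                  class = "flexconn_degenerate_error")
  }
  X <- scale(z_edges, center = TRUE, scale = scale.)
  sv <- svd(X)
  w <- sv$v[, 1]
  if (mean(w) < 0) w <- -w
  scores <- as.vector(X %*% w)
  names(scores) <- rownames(z_edges)
  flag <- ncol(z_edges) > nrow(z_edges)
  if (flag) {
    rlang::warn("More edges than subjects; PC1 is computed but unstable.")
  }
  structure(list(
    edges = colnames(z_edges) %||% paste0("e", seq_len(ncol(z_edges))),
    weights = stats::setNames(w, colnames(z_edges)),
    scores = scores,
    variance_explained = sv$d[1]^2 / sum(sv$d^2),
    more_edges_than_subjects = flag,
    scaled = scale.
  ), class = "subnetwork_component")
}

#' @export
print.subnetwork_component <- function(x, ...) {
  cat(sprintf("<subnetwork_component> %d edges, PC1 explains %.1f%% of variance\n",
              length(x$edges), 100 * x$variance_explained))
  invisible(x)
}

# Closed-form natural effects for a normal mediator and log-linear outcome.
med_effects_closed_form <- function(a0, a1, a2, b1, b2, b4, sigma_m, cbar,
                                    include_interaction) {
  if (!include_interaction) {
    log_nde <- b1
    log_nie <- a1 * b2
  } else {
    # exact lognormal moment: E[exp(k M)] = exp(k mu + k^2 sigma^2 / 2), so
    # the direct-effect contrast at M(0) picks up b4 (a0 + a2 Cbar) plus the
    # variance term (b2 b4 + b4^2 / 2) sigma_m^2
    log_nde <- b1 + b4 * (a0 + a2 * cbar) +
      (b2 * b4 + b4^2 / 2) * sigma_m^2
    log_nie <- (b2 + b4) * a1
  }
  log_total <- log_nde + log_nie
  list(
    rr_nde = exp(log_nde), rr_nie = exp(log_nie), rr_total = exp(log_total),
    pm_log = if (log_total != 0) log_nie / log_total else NA_real_,
    pm_excess_rr = if (exp(log_total) != 1) {
      exp(log_nde) * (exp(log_nie) - 1) / (exp(log_total) - 1)
    } else NA_real_
  )
}

fit_mediation_models <- function(x, m, y, covariate, include_interaction) {
  Xa <- cbind(intercept = 1, x = x, covariate = covariate)
  a_fit <- stats::lm.fit(Xa, m)
  a <- a_fit$coefficients
  sigma_m <- sqrt(sum(a_fit$residuals^2) / (length(m) - length(a)))
  Xb <- cbind(intercept = 1, x = x, m = m, covariate = covariate)
  if (include_interaction) Xb <- cbind(Xb, `x:m` = x * m)
  b_fit <- fit_poisson_glm(y, Xb)
  b <- stats::setNames(b_fit$estimate, b_fit$term)
  eff <- med_effects_closed_form(
    a0 = a[["intercept"]], a1 = a[["x"]], a2 = a[["covariate"]],
    b1 = b[["x"]], b2 = b[["m"]],
    b4 = if (include_interaction) b[["x:m"]] else 0,
    sigma_m = sigma_m, cbar = mean(covariate),
    include_interaction = include_interaction
  )
  list(a = a, sigma_m = sigma_m, b = b, b_fit = b_fit, eff = eff)
}

#' Counterfactual causal mediation with a Poisson count outcome
#'
#' Fits the mediator model `M = a0 + a1 X + a2 C + e` by ordinary least
#' squares (normal errors) and the outcome model
#' `log E[Y] = b0 + b1 X + b2 M + b3 C (+ b4 X*M)` by Poisson IRLS, then
#' reports the counterfactual natural direct and indirect effects on the
#' rate-ratio scale. Without an exposure-mediator interaction,
#' `RR_NIE = exp(a1 b2)` and `RR_NDE = exp(b1)`; with the interaction the
#' effects are conditional at the mean covariate,
#' `RR_NDE = exp(b1 + b4 (a0 + a2 Cbar) + (b2 b4 + b4^2/2) sigma_m^2)` (the
#' exact normal-moment form) and `RR_NIE = exp((b2 + b4) a1)`. The total effect decomposes as
#' `RR_total = RR_NDE * RR_NIE`, and the proportion mediated is reported on
#' the log scale (`pm_log = log RR_NIE / log RR_total`) and on the
#' excess-rate-ratio scale
#' (`pm_excess = RR_NDE (RR_NIE - 1) / (RR_total - 1)`).
#'
#' Inference is by nonparametric subject-resampling bootstrap (stratified by
#' exposure so group sizes are preserved), with percentile intervals and a
#' two-sided bootstrap p-value for the indirect effect.
#'
#' @param x Binary exposure indicator (0/1, or a two-level factor; the
#'   `AIE`/second level maps to 1).
#' @param m Numeric mediator score per subject.
#' @param y Count outcome per subject.
#' @param covariate Binary covariate (sex; reference `F` = 0).
#' @param include_interaction Include the `X * M` term? Default `FALSE`.
#' @param n_boot Bootstrap resamples (default 1000, minimum 200).
#' @param seed Integer seed for the bootstrap.
#' @param stratified Resample within exposure groups? Default `TRUE`.
#' @return Object of class `mediation_result`: lists `a_path` (coefficients,
#'   `sigma_m`), `b_path` (the `glm_fit` table), point estimates `rr_nde`,
#'   `rr_nie`, `rr_total`, `pm_log`, `pm_excess_rr`, bootstrap `ci` tibble,
#'   `p_indirect`, `inconsistent` flag, `n_redraws`, settings.
#' @export
causal_mediation <- function(x, m, y, covariate = NULL,
                             include_interaction = FALSE,
                             n_boot = 1000L, seed = 1L, stratified = TRUE) {
  if (is.factor(x) || is.character(x)) {
    f <- factor(x)
    if (nlevels(f) != 2) stop_flexconn("`x` must be binary.")
    x <- as.numeric(f == (if ("AIE" %in% levels(f)) "AIE" else levels(f)[2]))
  }
  if (!all(x %in% c(0, 1))) {
    stop_flexconn("`x` must be a binary 0/1 exposure.",
                  class = "flexconn_validation_error")
  }
  if (length(unique(x)) < 2) stop_flexconn("Both exposure groups are required.")
  if (is.null(covariate)) covariate <- rep(0, length(x))
  if (is.factor(covariate) || is.character(covariate)) {
    covariate <- as.numeric(factor(covariate)) - 1
  }
  n_boot <- check_scalar_int(n_boot, "n_boot", 200L)
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, length(covariate) == n)

  fit <- fit_mediation_models(x, m, y, covariate, include_interaction)
  eff <- fit$eff

  set.seed(check_scalar_int(seed, "seed", 0L))
  idx1 <- which(x == 1)
  idx0 <- which(x == 0)
  n_redraws <- 0L
  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("log_nde", "log_nie", "pm_log",
                                         "pm_excess_rr")))
  for (b in seq_len(n_boot)) {
    repeat {
      if (stratified) {
        idx <- c(sample(idx1, length(idx1), replace = TRUE),
                 sample(idx0, length(idx0), replace = TRUE))
      } else {
        idx <- sample.int(n, n, replace = TRUE)
      }
      if (length(unique(x[idx])) == 2) break
      n_redraws <- n_redraws + 1L
    }
    fb <- tryCatch(
      suppressWarnings(
        fit_mediation_models(x[idx], m[idx], y[idx], covariate[idx],
                             include_interaction)),
      error = function(e) NULL
    )
    if (is.null(fb)) { n_redraws <- n_redraws + 1L; next }
    boot[b, ] <- c(log(fb$eff$rr_nde), log(fb$eff$rr_nie),
                   fb$eff$pm_log, fb$eff$pm_excess_rr)
  }
  ok <- stats::complete.cases(boot[, c("log_nde", "log_nie")])
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE,
                                    names = FALSE)
  ci <- tibble::tibble(
    quantity = c("rr_nde", "rr_nie", "rr_total", "pm_log", "pm_excess_rr"),
    estimate = c(eff$rr_nde, eff$rr_nie, eff$rr_total, eff$pm_log,
                 eff$pm_excess_rr),
    ci_low = c(exp(qs(boot[ok, "log_nde"])[1]), exp(qs(boot[ok, "log_nie"])[1]),
               exp(qs(boot[ok, "log_nde"] + boot[ok, "log_nie"])[1]),
               qs(boot[ok, "pm_log"])[1], qs(boot[ok, "pm_excess_rr"])[1]),
    ci_high = c(exp(qs(boot[ok, "log_nde"])[2]), exp(qs(boot[ok, "log_nie"])[2]),
                exp(qs(boot[ok, "log_nde"] + boot[ok, "log_nie"])[2]),
                qs(boot[ok, "pm_log"])[2], qs(boot[ok, "pm_excess_rr"])[2])
  )
  lnie <- boot[ok, "log_nie"]
  p_indirect <- min(1, 2 * min(mean(lnie <= 0), mean(lnie >= 0)))
  inconsistent <- (eff$rr_nde - 1) * (eff$rr_nie - 1) < 0
  if (inconsistent) {
    rlang::warn(paste("Inconsistent mediation: direct and indirect effects",
                      "point in opposite directions; pm_excess_rr is not a",
                      "proportion."),
                class = "flexconn_inconsistent_mediation")
  }
  structure(list(
    a_path = list(coefficients = fit$a, sigma_m = fit$sigma_m),
    b_path = fit$b_fit,
    rr_nde = eff$rr_nde, rr_nie = eff$rr_nie, rr_total = eff$rr_total,
    pm_log = eff$pm_log, pm_excess_rr = eff$pm_excess_rr,
    ci = ci, p_indirect = p_indirect,
    boot = boot,
    inconsistent = inconsistent,
    n_redraws = n_redraws,
    settings = list(include_interaction = include_interaction,
                    n_boot = n_boot, seed = seed, stratified = stratified)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result>\n")
  cat(sprintf("  RR_NDE = %.3f, RR_NIE = %.3f, RR_total = %.3f\n",
              x$rr_nde, x$rr_nie, x$rr_total))
  cat(sprintf("  proportion mediated (log scale) = %.1f%%, bootstrap p(indirect) = %.4g\n",
              100 * x$pm_log, x$p_indirect))
  invisible(x)
}

#' Recover planted mediation parameters through the full pipeline
#'
#' Runs connectivity -> edgewise statistics -> edge selection -> PC1 ->
#' causal mediation on one synthetic dataset with known planted parameters,
#' and reports the estimates next to the planted truth. The mediator truth
#' for the indirect path is expressed through the planted-subnetwork mean-z
#' shift implied by the network effect.
#'
#' @param config A [synthetic_config()].
#' @param n_boot Bootstrap draws for the mediation stage (default 500).
#' @param seed Seed for the mediation bootstrap.
#' @param select_p Edge-selection threshold (default 0.1).
#' @return List with `estimates` (mediation_result), `selected_edges`,
#'   `planted_edges`, `edge_recovery` (fraction of planted edges selected),
#'   `truth` (planted parameters and implied mediator shift).
#' @export
recover_planted_mediation <- function(config = synthetic_config(),
                                      n_boot = 500L, seed = 1L,
                                      select_p = 0.1) {
  sim <- simulate_study(config)
  z <- edge_matrix(sim$conn, "z")
  stats_tbl <- edgewise_group_stats(z, sim$design)
  sel <- select_edges(stats_tbl, select_p, "exposure")
  if (length(sel) < 2) {
    stop_flexconn("Fewer than 2 edges selected; cannot build a subnetwork.")
  }
  pc <- subnetwork_pc1(z[, sel, drop = FALSE])
  med <- causal_mediation(
    x = sim$design$exposure, m = pc$scores, y = sim$counts$count,
    covariate = sim$design$sex, n_boot = n_boot, seed = seed
  )
  planted <- config$network$affected_edges
  base_z <- atanh(edge_values(config$network$base_corr)[planted])
  red_z <- atanh(edge_values(sim$truth$reduced_corr)[planted])
  list(
    estimates = med,
    subnetwork = pc,
    selected_edges = sel,
    planted_edges = planted,
    edge_recovery = mean(planted %in% sel),
    truth = list(mediation = config$mediation,
                 mediator_shift = mean(red_z - base_z))
  )
}
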