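#' Fit a Poisson log-link GLM with Wald rate-ratio intervals
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (convergence tolerance 1e-8 on the deviance change, at most 100
#' iterations). Effects are reported on the rate-ratio scale `Exp(B)` with
#' Wald 95% intervals `exp(b +/- 1.96 * SE)`, the style of standard
#' behavioral-statistics output tables.
#'
#' @param y Non-negative integer counts, one per subject.
#' @param design_matrix Numeric matrix (subjects x terms), full column rank.
#'   Include a column of ones for the intercept. Column names label the terms.
#' @return A tibble of class `glm_fit` with one row per term: `term`,
#'   `estimate` (log scale), `se`, `exp_b`, `ci_low`, `ci_high`, `p`, plus
#'   attributes `deviance` and `converged`.
#' @export
#' @examples
#' y <- c(2, 2, 2, 4, 4, 4)
#' X <- cbind(intercept = 1, group = rep(0:1, each = 3))
#' fit_poisson_glm(y, X)
fit_poisson_glm <- function(y, design_matrix) {
  X <- as.matrix(design_matrix)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop_flexconn("`y` must be finite non-negative integer counts.",
                  class = "flexconn_validation_error")
  }
  if (length(y) != nrow(X)) {
    stop_flexconn("`y` and `design_matrix` disagree on the number of subjects.")
  }
  if (qr(X)$rank < ncol(X)) {
    stop_flexconn("Design matrix is rank deficient.",
                  class = "flexconn_rank_error")
  }
  fit <- stats::glm.fit(x = X, y = y, family = stats::poisson(),
                        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  b <- fit$coefficients
  # Wald SEs from the observed information at the IRLS optimum (dispersion 1)
  XtWX <- crossprod(X * sqrt(fit$weights))
  cov_unscaled <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(cov_unscaled))
  zcrit <- 1.96
  res <- tibble::tibble(
    term = colnames(X),
    estimate = unname(b),
    se = se,
    exp_b = exp(unname(b)),
    ci_low = exp(unname(b) - zcrit * se),
    ci_high = exp(unname(b) + zcrit * se),
    p = 2 * stats::pnorm(-abs(unname(b) / se))
  )
  attr(res, "deviance") <- fit$deviance
  # a fitted rate at the boundary (separation, e.g. an all-zero group) means
  # the MLE diverges even though IRLS reports deviance convergence
  separated <- any(fit$fitted.values < 1e-8) || any(abs(b) > 12)
  attr(res, "converged") <- isTRUE(fit$converged) && all(is.finite(se)) &&
    !separated
  if (!attr(res, "converged")) {
    rlang::warn("Poisson GLM did not converge (or has non-finite standard errors).",
                class = "flexconn_nonconvergence")
  }
  class(res) <- c("glm_fit", class(res))
  res
}

#' Two-way between-subjects ANOVA (2 x 2)
#'
#' Main effects and interaction for two crossed binary factors, using Type-II
#' sums of squares (identical to the textbook Type-I decomposition in balanced
#' designs). A fit with (numerically) zero residual variance is returned with
#' infinite F and a `degenerate` flag rather than failing.
#'
#' @param y Numeric response, one per subject.
#' @param factor_a,factor_b Binary factors (any two-level coding).
#' @param effect_names Labels for the three effects in the output
#'   (defaults `factor_a`, `factor_b`, `interaction`).
#' @param ss_type Sums-of-squares type passed to [car::Anova()] (2 or 3).
#' @return A tibble of class `anova_result` with columns `effect`, `F`,
#'   `df1`, `df2`, `p`, `degenerate`.
#' @export
two_way_anova <- function(y, factor_a, factor_b,
                          effect_names = c("factor_a", "factor_b", "interaction"),
                          ss_type = 2) {
  if (any(!is.finite(y))) stop_flexconn("`y` must be finite.")
  if (stats::sd(y) == 0) {
    stop_flexconn("`y` is constant; ANOVA is undefined.",
                  class = "flexconn_degenerate_error")
  }
  A <- factor(factor_a)
  B <- factor(factor_b)
  if (nlevels(A) != 2L || nlevels(B) != 2L) {
    stop_flexconn("Both factors must have exactly two observed levels.")
  }
  cell_n <- table(A, B)
  if (any(cell_n < 2L)) {
    stop_flexconn("Every sex x exposure cell needs at least 2 subjects.",
                  class = "flexconn_validation_error")
  }
  fit <- stats::lm(y ~ A * B)
  rss <- sum(stats::residuals(fit)^2)
  df2 <- fit$df.residual
  if (rss < 1e-12 * max(1, sum(y^2))) {
    # zero within-cell variance: F ratios are unbounded
    return(tibble::tibble(
      effect = effect_names, F = Inf, df1 = 1L, df2 = df2,
      p = 0, degenerate = TRUE
    ) |> structure(class = c("anova_result", class(tibble::tibble()))))
  }
  tab <- car::Anova(fit, type = ss_type)
  rows <- c("A", "B", "A:B")
  out <- tibble::tibble(
    effect = effect_names,
    F = tab[rows, "F value"],
    df1 = as.integer(tab[rows, "Df"]),
    df2 = df2,
    p = tab[rows, "Pr(>F)"],
    degenerate = FALSE
  )
  class(out) <- c("anova_result", class(out))
  out
}

#' Two-sided correlation p-value from the symmetric beta distribution
#'
#' Under the null of no correlation with independent bivariate-normal samples,
#' a Pearson correlation from `n` observations follows a symmetric beta
#' distribution on \[-1, 1\] with equal shape parameters `a = b = n/2 - 1`.
#' The two-sided p-value is `2 * min(F(r), 1 - F(r))` for that CDF. This is
#' algebraically identical to the classical t-test on
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param r Pearson correlation(s) in \[-1, 1\].
#' @param n Sample size(s); must exceed 2 (shapes are positive), and should
#'   exceed 4 for shapes greater than 1.
#' @return Two-sided p-value(s) in (0, 1].
#' @export
#' @examples
#' corr_pvalue_beta(0.5, 20)
corr_pvalue_beta <- function(r, n) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop_flexconn("`r` must lie in [-1, 1].", class = "flexconn_validation_error")
  }
  if (any(n <= 2)) {
    stop_flexconn("`n` must exceed 2 for the beta shapes to be positive.",
                  class = "flexconn_validation_error")
  }
  shape <- n / 2 - 1
  F <- stats::pbeta((r + 1) / 2, shape, shape)
  pmin(1, 2 * pmin(F, 1 - F))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; monotone in rank and capped at 1.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_flexconn("p-values must lie in [0, 1].", class = "flexconn_validation_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Bonferroni adjusted p-values
#'
#' `q = min(1, m * p)` for `m` comparisons.
#'
#' @inheritParams bh_fdr
#' @return Adjusted values, capped at 1.
#' @export
bonferroni <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_flexconn("p-values must lie in [0, 1].", class = "flexconn_validation_error")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Label p-values with report significance markers
#'
#' Significance at p <= 0.05 and marginal significance at p <= 0.10,
#' the labeling convention used in the report tables.
#'
#' @param p Numeric p-values.
#' @return Character vector: `"*"`, `"~"` (marginal) or `""`.
#' @export
significance_label <- function(p) {
  ifelse(p <= 0.05, "*", ifelse(p <= 0.10, "~", ""))
}

#' Effects table for a 2 x 2 Poisson GLM, report style
#'
#' Fits `count ~ exposure * sex` with a log link and returns the three
#' effects in a tidy table with `Exp(B)` and its Wald interval, mirroring the
#' layout of standard behavioral results tables.
#'
#' @param y Counts per subject.
#' @param exposure,sex Binary factors/indicators per subject.
#' @return Tibble with columns `effect`, `p`, `exp_b`, `ci_low`, `ci_high`,
#'   `signif`.
#' @export
glm_effects_table <- function(y, exposure, sex) {
  fx <- factor(exposure)
  # exposure indicator: AIE = 1 when present, otherwise the second level
  x <- as.numeric(fx == (if ("AIE" %in% levels(fx)) "AIE" else levels(fx)[2]))
  c_ <- as.numeric(factor(sex)) - 1  # reference F = 0
  X <- cbind(intercept = 1, exposure = x, sex = c_, `exposure:sex` = x * c_)
  fit <- fit_poisson_glm(y, X)
  out <- fit[fit$term != "intercept",
             c("term", "p", "exp_b", "ci_low", "ci_high")]
  names(out)[1] <- "effect"
  out$signif <- significance_label(out$p)
  tibble::as_tibble(out)
}
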