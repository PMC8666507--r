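# Edgewise group statistics with link-based permutation family-wise error
# control (network-based statistics), and edge-behavior correlation with
# beta-distribution p-values + FDR.

# Pooled-variance two-sample t statistics for many permutations at once.
# z: n x E matrix; P: n_perm x n 0/1 indicator of group-1 membership (every
# row must contain the same group-1 count). Returns an n_perm x E matrix of
# t values (group1 mean - group0 mean, pooled SE).
perm_t_matrix <- function(z, P) {
  n <- nrow(z)
  n1 <- sum(P[1, ])
  n0 <- n - n1
  tot <- colSums(z)
  tot2 <- colSums(z^2)
  S1 <- P %*% z                      # n_perm x E group-1 sums
  Q1 <- P %*% (z^2)
  S0 <- matrix(tot, nrow(P), ncol(z), byrow = TRUE) - S1
  Q0 <- matrix(tot2, nrow(P), ncol(z), byrow = TRUE) - Q1
  m1 <- S1 / n1
  m0 <- S0 / n0
  ss1 <- Q1 - S1^2 / n1
  ss0 <- Q0 - S0^2 / n0
  sp2 <- (ss1 + ss0) / (n - 2)
  (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

as_group_indicator <- function(labels) {
  f <- factor(labels)
  if (nlevels(f) != 2L) {
    stop_flexconn("Group labels must have exactly two levels.",
                  class = "flexconn_validation_error")
  }
  # Exposure convention: "AIE" (or the first level otherwise) is group 1 so
  # that t = exposure mean - control mean.
  lev1 <- if ("AIE" %in% levels(f)) "AIE" else levels(f)[1]
  as.numeric(f == lev1)
}

#' Edgewise group statistics (two-way ANOVA + exposure t) per edge
#'
#' For every canonical edge: a 2 x 2 between-subjects ANOVA of the Fisher-z
#' values on exposure and sex, plus the pooled two-sample exposure t
#' statistic (sexes pooled) used for suprathresholding. The t sign convention
#' is exposure minus control; `t_value` reports the magnitude with a
#' `direction` column.
#'
#' @param z Subjects x edges numeric matrix (as from [edge_matrix()]), rows
#'   aligned with `design`.
#' @param design Design table with `subject_id`, `sex`, `exposure`.
#' @return Tibble of class `edge_stats` with one row per edge: `edge`,
#'   `t_signed`, `t_value`, `direction`, `p_t`, `F_exposure`, `p_exposure`,
#'   `F_sex`, `p_sex`, `F_interaction`, `p_interaction`, `degenerate`.
#' @export
edgewise_group_stats <- function(z, design) {
  if (nrow(z) != nrow(design)) {
    stop_flexconn("One matrix row per design subject is required.",
                  class = "flexconn_validation_error")
  }
  if (!is.null(rownames(z)) &&
      !identical(rownames(z), as.character(design$subject_id))) {
    stop_flexconn("Subject order in `z` does not match `design`.",
                  class = "flexconn_validation_error")
  }
  x <- as_group_indicator(design$exposure)
  t_obs <- as.vector(perm_t_matrix(z, matrix(x, nrow = 1)))
  n <- nrow(z)
  p_t <- 2 * stats::pt(-abs(t_obs), df = n - 2)
  anovas <- lapply(seq_len(ncol(z)), function(e) {
    tryCatch(
      two_way_anova(z[, e], design$exposure, design$sex,
                    effect_names = c("exposure", "sex", "interaction")),
      flexconn_degenerate_error = function(err) {
        tibble::tibble(effect = c("exposure", "sex", "interaction"),
                       F = 0, df1 = 1L, df2 = n - 4L, p = 1, degenerate = TRUE)
      }
    )
  })
  pick <- function(eff, col) {
    vapply(anovas, function(a) a[[col]][a$effect == eff], numeric(1))
  }
  out <- tibble::tibble(
    edge = colnames(z) %||% paste0("e", seq_len(ncol(z))),
    t_signed = t_obs,
    t_value = abs(t_obs),
    direction = ifelse(t_obs < 0, "reduced", "increased"),
    p_t = p_t,
    F_exposure = pick("exposure", "F"),
    p_exposure = pick("exposure", "p"),
    F_sex = pick("sex", "F"),
    p_sex = pick("sex", "p"),
    F_interaction = pick("interaction", "F"),
    p_interaction = pick("interaction", "p"),
    degenerate = vapply(anovas, function(a) any(a$degenerate), logical(1))
  )
  class(out) <- c("edge_stats", class(out))
  out
}

# All C(n, n1) distinct group-1 assignments as an indicator matrix.
exhaustive_assignments <- function(n, n1) {
  combos <- utils::combn(n, n1)
  P <- matrix(0, ncol(combos), n)
  for (k in seq_len(ncol(combos))) P[k, combos[, k]] <- 1
  P
}

#' Network-based statistics: permutation family-wise error control
#'
#' Link-based variant (default): the corrected p-value of edge `e` is the
#' permutation probability that the maximum absolute pooled t over all edges
#' meets or exceeds `|t_e|`, over `n_perm` relabelings of the group labels
#' (the observed labeling is included in the null). Component variant: the
#' absolute-t map is thresholded at the critical t for `supra_p`, connected
#' components are formed on the ROI graph, and the corrected p of each
#' observed component is the permutation probability of a null maximum
#' component size (in edges) at least as large.
#'
#' If `n_perm` meets or exceeds the number of distinct label assignments the
#' engine switches to exhaustive enumeration and the p-values are exact.
#'
#' @param z Subjects x edges matrix of Fisher-z values.
#' @param labels Two-level group labels (exposure), one per subject.
#' @param supra_p Edge-level suprathreshold (default 0.05, two-tailed).
#' @param n_perm Number of permutations (default 5000, minimum 100).
#' @param seed Integer seed for the permutation draw.
#' @param variant `"link"` (default) or `"component"`.
#' @param edges Edge metadata tibble (from [edge_table()]); required for the
#'   component variant, inferred from `colnames(z)` when `NULL`.
#' @return Object of class `nbs_result`: list with `table` (per-edge tibble:
#'   `edge`, `t_signed`, `p_uncorrected`, `suprathreshold`, `corrected_p`,
#'   `significant`), `null_max_stat` summary, `n_perm` (effective),
#'   `exhaustive`, `variant`, `seed`, and for the component variant
#'   `components`.
#' @export
nbs_fwe <- function(z, labels, supra_p = 0.05, n_perm = 5000L, seed = 1L,
                    variant = c("link", "component"), edges = NULL) {
  variant <- match.arg(variant)
  x <- as_group_indicator(labels)
  n <- length(x)
  n1 <- sum(x)
  if (min(n1, n - n1) < 2) {
    stop_flexconn("Each group needs at least 2 subjects.",
                  class = "flexconn_validation_error")
  }
  n_perm <- check_scalar_int(n_perm, "n_perm", 100L)
  check_prob(supra_p, "supra_p")
  n_assign <- choose(n, n1)
  exhaustive <- n_perm >= n_assign
  if (exhaustive) {
    P <- exhaustive_assignments(n, n1)
  } else {
    set.seed(check_scalar_int(seed, "seed", 0L))
    P <- matrix(0, n_perm, n)
    P[1, ] <- x  # observed labeling included in the null
    for (k in 2:n_perm) P[k, sample.int(n, n1)] <- 1
  }
  Tmat <- perm_t_matrix(z, P)
  t_obs <- as.vector(perm_t_matrix(z, matrix(x, nrow = 1)))
  abs_T <- abs(Tmat)
  df <- n - 2
  p_unc <- 2 * stats::pt(-abs(t_obs), df)
  supra <- p_unc < supra_p
  n_eff <- nrow(P)

  if (variant == "link") {
    max_null <- apply(abs_T, 1, max)
    # tiny slack so assignments whose max statistic equals |t_e| up to
    # floating-point noise (e.g. the label-swapped observed assignment)
    # count as exceedances
    corrected <- vapply(abs(t_obs), function(t0) {
      mean(max_null >= t0 - 1e-10 * max(1, t0))
    }, numeric(1))
    tab <- tibble::tibble(
      edge = colnames(z) %||% paste0("e", seq_len(ncol(z))),
      t_signed = t_obs,
      p_uncorrected = p_unc,
      suprathreshold = supra,
      corrected_p = corrected,
      significant = supra & corrected < 0.05
    )
    components <- NULL
  } else {
    if (is.null(edges)) {
      if (is.null(colnames(z))) {
        stop_flexconn("Component variant needs `edges` metadata or edge names.")
      }
      parts <- strsplit(colnames(z), "-", fixed = TRUE)
      rois <- unique(unlist(parts))
      edges <- tibble::tibble(
        edge = colnames(z),
        i = match(vapply(parts, `[`, character(1), 1), rois),
        j = match(vapply(parts, `[`, character(1), 2), rois)
      )
    }
    t_crit <- stats::qt(1 - supra_p / 2, df)
    comp_of <- function(tvec) {
      on <- which(abs(tvec) > t_crit)
      if (!length(on)) return(list(sizes = integer(0), membership = NULL))
      g <- igraph::graph_from_edgelist(
        cbind(edges$i[on], edges$j[on]), directed = FALSE)
      cl <- igraph::components(g)
      # component size counted in edges; renumber so ids are contiguous over
      # components that actually contain suprathreshold edges
      edge_comp <- cl$membership[edges$i[on]]
      ids <- sort(unique(edge_comp))
      idx <- match(edge_comp, ids)
      list(sizes = as.integer(tabulate(idx, nbins = length(ids))),
           membership = stats::setNames(idx, edges$edge[on]))
    }
    obs <- comp_of(t_obs)
    max_null <- vapply(seq_len(n_eff), function(k) {
      s <- comp_of(Tmat[k, ])$sizes
      if (length(s)) max(s) else 0L
    }, integer(1))
    comp_p <- vapply(obs$sizes, function(s) mean(max_null >= s), numeric(1))
    corrected <- rep(NA_real_, ncol(z))
    if (length(obs$sizes)) {
      idx <- match(names(obs$membership), colnames(z) %||% edges$edge)
      corrected[idx] <- comp_p[obs$membership]
    }
    tab <- tibble::tibble(
      edge = colnames(z) %||% edges$edge,
      t_signed = t_obs,
      p_uncorrected = p_unc,
      suprathreshold = abs(t_obs) > t_crit,
      corrected_p = corrected,
      significant = !is.na(corrected) & corrected < 0.05
    )
    components <- tibble::tibble(component = seq_along(obs$sizes),
                                 n_edges = obs$sizes, corrected_p = comp_p)
  }
  structure(list(
    table = tab,
    null_max_stat = summary(if (variant == "link") max_null else
      as.numeric(max_null)),
    null_max = if (variant == "link") max_null else as.numeric(max_null),
    n_perm = n_eff,
    exhaustive = exhaustive,
    variant = variant,
    seed = seed,
    supra_p = supra_p,
    components = components
  ), class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s-based FWE, %d permutations%s, seed %d\n",
              x$variant, x$n_perm,
              if (x$exhaustive) " (exhaustive)" else "", x$seed))
  sig <- x$table$edge[x$table$significant]
  cat(sprintf("  significant edges (corrected p < 0.05): %s\n",
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

#' Edge-behavior correlation with beta p-values and FDR correction
#'
#' Pearson correlation between a per-subject behavior score and each edge's
#' Fisher-z connectivity, with two-sided p-values from the symmetric beta
#' null distribution ([corr_pvalue_beta()]) and Benjamini-Hochberg q-values
#' over the edges. If a design is supplied, per-group (sex, exposure)
#' stratified correlations are included for scatter reporting.
#'
#' @param z Subjects x edges matrix of Fisher-z values.
#' @param behavior Finite numeric score per subject (e.g. active errors).
#' @param design Optional design table for stratified correlations.
#' @return Tibble of class `edge_behavior_corr`: per edge `edge`,
#'   `r_behavior`, `p_beta`, `q_fdr`, `n`, plus stratified `r_<level>`
#'   columns when `design` is given.
#' @export
edge_behavior_correlation <- function(z, behavior, design = NULL) {
  n <- nrow(z)
  if (length(behavior) != n) {
    stop_flexconn("One behavior score per subject is required.")
  }
  if (any(!is.finite(behavior))) {
    stop_flexconn("Behavior scores must be finite.",
                  class = "flexconn_validation_error")
  }
  if (n < 5) {
    stop_flexconn("At least 5 subjects are required.",
                  class = "flexconn_validation_error")
  }
  if (stats::sd(behavior) == 0) {
    stop_flexconn("Behavior vector is constant; correlation undefined.",
                  class = "flexconn_degenerate_error")
  }
  r <- as.vector(stats::cor(behavior, z))
  out <- tibble::tibble(
    edge = colnames(z) %||% paste0("e", seq_len(ncol(z))),
    r_behavior = r,
    p_beta = corr_pvalue_beta(r, n),
    q_fdr = bh_fdr(corr_pvalue_beta(r, n)),
    n = n
  )
  if (!is.null(design)) {
    for (fac in c("sex", "exposure")) {
      for (lev in unique(design[[fac]])) {
        sel <- design[[fac]] == lev
        out[[paste0("r_", lev)]] <- if (sum(sel) >= 3 &&
                                        stats::sd(behavior[sel]) > 0) {
          as.vector(stats::cor(behavior[sel], z[sel, , drop = FALSE]))
        } else {
          NA_real_
        }
      }
    }
  }
  class(out) <- c("edge_behavior_corr", class(out))
  out
}
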