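# Seeded synthetic-data generators: balanced 2x2 designs, multivariate-normal
# ROI signals with a planted exposure-reduced edge subset, Poisson set-shift
# counts driven by a planted mediation path, Bernoulli trial sequences, and
# Pavlovian event logs. Every generator is a pure function of its arguments
# and seed.

#' Planted group-connectivity effect
#'
#' Describes the population ROI correlation structure and the edge subset on
#' which the exposure group's correlations are reduced. The control group
#' samples from `base_corr`; the exposure group samples from `base_corr`
#' minus `delta` on the affected edges, repaired to the nearest
#' positive-definite correlation matrix (eigenvalues clipped at `1e-6`,
#' then renormalized to unit diagonal).
#'
#' Defaults emulate the qualitative finding the pipeline is built around: an
#' exchangeable positive base correlation (0.35) across eight ROIs, with
#' connectivity reduced (delta = 0.3) on the five accumbens edges
#' PrL-NAc, S1-NAc, NAc-CPu, NAc-HippD and NAc-Thal.
#'
#' Beyond the group effect, each subject carries a stable subnetwork-strength
#' factor: a shared offset (SD `subject_sd` on the Fisher-z scale) added to
#' the affected edges' correlations before sampling. Stable between-subject
#' variance in connectivity is what makes cross-subject brain-behavior
#' correlation - and mediation through connectivity - estimable at all;
#' without it the mediator would vary only by correlation-estimation noise.
#'
#' @param roi_names Ordered ROI labels.
#' @param base_corr R x R symmetric positive-definite correlation matrix with
#'   unit diagonal. Default: exchangeable with off-diagonal 0.35.
#' @param affected_edges Character vector of `"A-B"` edge labels (any
#'   orientation).
#' @param delta Correlation reduction applied to each affected edge.
#' @param subject_sd SD of the per-subject shared Fisher-z offset on the
#'   affected edges (default 0.2; 0 disables subject heterogeneity).
#' @param edge_sd SD of independent per-subject, per-edge Fisher-z offsets
#'   applied to every edge (default 0.15); models stable idiosyncratic
#'   connectivity differences between subjects beyond the shared subnetwork
#'   factor.
#' @return Object of class `planted_network_effect`.
#' @export
planted_network_effect <- function(roi_names = default_rois(),
                                   base_corr = NULL,
                                   affected_edges = c("PrL-NAc", "S1-NAc",
                                                      "NAc-CPu", "NAc-HippD",
                                                      "NAc-Thal"),
                                   delta = 0.3, subject_sd = 0.2,
                                   edge_sd = 0.15) {
  R <- length(roi_names)
  if (is.null(base_corr)) {
    base_corr <- matrix(0.35, R, R)
    diag(base_corr) <- 1
  }
  base_corr <- as.matrix(base_corr)
  if (!isTRUE(all.equal(base_corr, t(base_corr))) ||
      !isTRUE(all.equal(unname(diag(base_corr)), rep(1, R)))) {
    stop_flexconn("`base_corr` must be symmetric with unit diagonal.",
                  class = "flexconn_validation_error")
  }
  ev <- eigen(base_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_flexconn(sprintf(
      "`base_corr` is not positive definite (smallest eigenvalue %.3e).",
      min(ev)), class = "flexconn_validation_error")
  }
  if (!is.numeric(delta) || delta < 0 || delta >= 2) {
    stop_flexconn("`delta` must be a non-negative correlation reduction.",
                  class = "flexconn_validation_error")
  }
  if (!is.numeric(subject_sd) || subject_sd < 0 ||
      !is.numeric(edge_sd) || edge_sd < 0) {
    stop_flexconn("`subject_sd` and `edge_sd` must be non-negative.",
                  class = "flexconn_validation_error")
  }
  dimnames(base_corr) <- list(roi_names, roi_names)
  affected_edges <- canonical_edges(affected_edges, roi_names)
  structure(list(roi_names = roi_names, base_corr = base_corr,
                 affected_edges = affected_edges, delta = delta,
                 subject_sd = subject_sd, edge_sd = edge_sd),
            class = "planted_network_effect")
}

#' Exposure-group correlation matrix implied by a planted effect
#'
#' Subtracts `delta` on the affected edges, then repairs to the nearest
#' positive-definite correlation matrix by clipping eigenvalues at
#' `eig_floor` and renormalizing to unit diagonal.
#'
#' @param effect A [planted_network_effect()].
#' @param eig_floor Eigenvalue floor used in the repair (default 1e-6).
#' @return Correlation matrix for the exposure group, with attribute
#'   `repaired` indicating whether clipping was needed.
#' @export
reduced_corr <- function(effect, eig_floor = 1e-6) {
  stopifnot(inherits(effect, "planted_network_effect"))
  m <- effect$base_corr
  edges <- edge_table(effect$roi_names)
  sel <- edges[edges$edge %in% effect$affected_edges, , drop = FALSE]
  m[cbind(sel$i, sel$j)] <- m[cbind(sel$i, sel$j)] - effect$delta
  m[cbind(sel$j, sel$i)] <- m[cbind(sel$i, sel$j)]
  e <- eigen(m, symmetric = TRUE)
  repaired <- min(e$values) < eig_floor
  if (repaired) {
    vals <- pmax(e$values, eig_floor)
    m <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(m))
    if (any(d <= 0)) {
      stop_flexconn(sprintf(
        "Correlation matrix not repairable (eigenvalue %.3e).", min(e$values)),
        class = "flexconn_validation_error")
    }
    m <- m / tcrossprod(d)
    dimnames(m) <- dimnames(effect$base_corr)
  }
  structure(m, repaired = repaired)
}

#' Planted mediation parameters
#'
#' Parameters of the exposure -> mediator -> count-outcome generative model:
#' the mediator is normal, `M = a0 + a1 X + N(0, sigma_m^2)`, and the outcome
#' is `Y ~ Poisson(exp(b0 + b1 X + b2 M + b3 C))` with `X` the exposure
#' indicator and `C` the sex indicator.
#'
#' Defaults are calibrated to desk-scale test power, with signs matching the
#' modeled phenomenon: exposure lowers the connectivity mediator
#' (`a1 < 0`) and lower connectivity raises the error rate (`b2 < 0`),
#' around a baseline of `exp(b0) = 10` active errors.
#'
#' @param a1 Exposure -> mediator shift (mediator units).
#' @param b0 Log baseline rate. @param b1 Direct exposure log-rate effect.
#' @param b2 Mediator log-rate slope. @param b3 Sex log-rate effect.
#' @param sigma_m Mediator residual SD (> 0).
#' @param a0 Mediator baseline (default 0).
#' @return Object of class `planted_mediation`.
#' @export
planted_mediation <- function(a1 = -0.25, b0 = log(10), b1 = 0.2, b2 = -0.75,
                              b3 = 0.1, sigma_m = 0.2, a0 = 0) {
  if (!is.numeric(sigma_m) || sigma_m <= 0) {
    stop_flexconn("`sigma_m` must be positive.",
                  class = "flexconn_validation_error")
  }
  if (exp(b0) > 1e6) {
    stop_flexconn("`exp(b0)` is outside the sane baseline-rate range.",
                  class = "flexconn_validation_error")
  }
  structure(list(a0 = a0, a1 = a1, b0 = b0, b1 = b1, b2 = b2, b3 = b3,
                 sigma_m = sigma_m),
            class = "planted_mediation")
}

#' Synthetic study configuration
#'
#' Bundles the design size, scan geometry and planted effects. Identical
#' configurations (including the seed) yield bit-identical datasets.
#'
#' @param n_per_cell Subjects per sex x exposure cell (default 10, i.e. 40
#'   subjects, the scale of a rodent imaging subsample).
#' @param n_timepoints Time points per scan (default 900: a 30-min scan at
#'   TR 2 s).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param seed Master integer seed.
#' @param network A [planted_network_effect()].
#' @param mediation A [planted_mediation()].
#' @param ar1 Optional AR(1) coefficient for the ROI signals (default 0,
#'   i.e. temporally white; see the methods vignette).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_cell = 10L, n_timepoints = 900L,
                             tr_seconds = 2, seed = 1L,
                             network = planted_network_effect(),
                             mediation = planted_mediation(),
                             ar1 = 0) {
  n_per_cell <- check_scalar_int(n_per_cell, "n_per_cell", 1L)
  n_timepoints <- check_scalar_int(n_timepoints, "n_timepoints", 2L)
  seed <- check_scalar_int(seed, "seed", 0L)
  stopifnot(inherits(network, "planted_network_effect"),
            inherits(mediation, "planted_mediation"))
  if (abs(ar1) >= 1) stop_flexconn("`ar1` must lie in (-1, 1).")
  structure(list(n_per_cell = n_per_cell, n_timepoints = n_timepoints,
                 tr_seconds = tr_seconds, seed = seed, network = network,
                 mediation = mediation, ar1 = ar1),
            class = "synthetic_config")
}

#' Generate a balanced 2 x 2 design table
#'
#' `4 * n_per_cell` subjects, exactly `n_per_cell` per sex x exposure cell.
#' The layout is deterministic (cells in fixed order); the `seed` argument is
#' accepted for interface symmetry with the other generators.
#'
#' @param n_per_cell Subjects per cell (>= 1).
#' @param seed Integer seed (unused by the deterministic layout).
#' @return Tibble with columns `subject_id`, `sex` (`F`/`M`), `exposure`
#'   (`AIE`/`Wat`).
#' @export
#' @examples
#' generate_design(2)
generate_design <- function(n_per_cell, seed = 1L) {
  n_per_cell <- check_scalar_int(n_per_cell, "n_per_cell", 1L)
  cells <- expand.grid(sex = c("F", "M"), exposure = c("AIE", "Wat"),
                       stringsAsFactors = FALSE)
  design <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(nrow(design))),
    sex = design$sex,
    exposure = design$exposure
  )
}

# Deterministic per-subject sub-seed: master seed plus subject counter, so
# adding/removing subjects never shuffles other subjects' draws.
subject_seed <- function(seed, i) as.integer((seed + i) %% .Machine$integer.max)

#' Generate per-subject ROI time series with a planted group effect
#'
#' Each subject receives a T x R draw from a zero-mean multivariate normal
#' whose correlation is `base_corr` (control group `Wat`) or the
#' positive-definite-repaired reduced matrix (exposure group `AIE`).
#' Per-subject sub-seeds derive deterministically from the master seed.
#'
#' @param design Design table from [generate_design()].
#' @param effect A [planted_network_effect()].
#' @param n_timepoints Time points per subject (> number of ROIs).
#' @param seed Master seed.
#' @param tr_seconds Repetition time, stored on each series.
#' @param ar1 AR(1) coefficient applied to the innovations (0 = white).
#' @return Named list of [roi_timeseries()] objects, one per subject.
#' @export
generate_roi_timeseries <- function(design, effect, n_timepoints = 900L,
                                    seed = 1L, tr_seconds = 2, ar1 = 0) {
  stopifnot(inherits(effect, "planted_network_effect"))
  R <- length(effect$roi_names)
  n_timepoints <- check_scalar_int(n_timepoints, "n_timepoints", 2L)
  if (n_timepoints <= R) {
    stop_flexconn(sprintf("Need n_timepoints (%d) > number of ROIs (%d).",
                          n_timepoints, R),
                  class = "flexconn_validation_error")
  }
  corr_wat <- effect$base_corr
  corr_aie <- unclass(reduced_corr(effect))
  edges <- edge_table(effect$roi_names)
  aff <- edges[edges$edge %in% effect$affected_edges, , drop = FALSE]
  n_edge <- nrow(edges)
  subject_corr <- function(group_corr, u, e_off) {
    if (u == 0 && all(e_off == 0)) return(group_corr)
    m <- group_corr
    zz <- atanh(m[cbind(edges$i, edges$j)]) + e_off
    if (u != 0 && nrow(aff) > 0) {
      zz[edges$edge %in% effect$affected_edges] <-
        zz[edges$edge %in% effect$affected_edges] + u
    }
    m[cbind(edges$i, edges$j)] <- tanh(zz)
    m[cbind(edges$j, edges$i)] <- m[cbind(edges$i, edges$j)]
    pd_repair(m)
  }
  out <- vector("list", nrow(design))
  names(out) <- design$subject_id
  for (i in seq_len(nrow(design))) {
    set.seed(subject_seed(seed, i))
    u <- if (effect$subject_sd > 0) stats::rnorm(1, 0, effect$subject_sd) else 0
    e_off <- if (effect$edge_sd > 0) {
      stats::rnorm(n_edge, 0, effect$edge_sd)
    } else {
      numeric(n_edge)
    }
    innov <- matrix(stats::rnorm(n_timepoints * R), n_timepoints, R)
    if (ar1 != 0) {
      innov <- apply(innov, 2, function(e) {
        as.numeric(stats::filter(e, ar1, method = "recursive"))
      })
    }
    grp <- if (design$exposure[i] == "AIE") corr_aie else corr_wat
    ch <- chol(subject_corr(grp, u, e_off))
    out[[i]] <- roi_timeseries(innov %*% ch, effect$roi_names, tr_seconds,
                               design$subject_id[i])
  }
  out
}

# Clip eigenvalues at a small floor and renormalize to unit diagonal.
pd_repair <- function(m, eig_floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(m)
  vals <- pmax(e$values, eig_floor)
  r <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  dimnames(r) <- dimnames(m)
  r
}

#' Generate Poisson set-shift error counts from a planted mediation model
#'
#' `Y_i ~ Poisson(exp(b0 + b1 X_i + b2 M_i + b3 C_i))` with `X` the exposure
#' indicator (`AIE` = 1), `M` the per-subject mediator score and `C` the sex
#' indicator (`M` = 1, reference `F` = 0).
#'
#' @param design Design table.
#' @param mediator_scores Numeric vector, one mediator value per subject (in
#'   design order).
#' @param params A [planted_mediation()].
#' @param seed Integer seed.
#' @return Tibble with `subject_id` and `count`.
#' @export
generate_setshift_counts <- function(design, mediator_scores, params,
                                     seed = 1L) {
  stopifnot(inherits(params, "planted_mediation"))
  if (length(mediator_scores) != nrow(design)) {
    stop_flexconn("Need exactly one mediator score per subject.",
                  class = "flexconn_validation_error")
  }
  x <- as.numeric(design$exposure == "AIE")
  c_ <- as.numeric(design$sex == "M")
  eta <- params$b0 + params$b1 * x + params$b2 * mediator_scores +
    params$b3 * c_
  if (any(!is.finite(eta)) || any(exp(eta) > 1e9)) {
    stop_flexconn("Poisson rate overflow: exp(linear predictor) exceeds 1e9.",
                  class = "flexconn_overflow_error")
  }
  set.seed(check_scalar_int(seed, "seed", 0L))
  tibble::tibble(subject_id = design$subject_id,
                 count = stats::rpois(nrow(design), exp(eta)))
}

#' Generate a Bernoulli set-shift trial sequence
#'
#' Choices are correct with probability `p_correct_pre` before the first
#' correct choice and `p_correct_post` afterwards (a two-regime caricature of
#' reversal learning). The sequence ends when `criterion_k` consecutive
#' correct choices occur, or at `max_trials` with the criterion flagged as
#' not reached.
#'
#' @param p_correct_pre,p_correct_post Success probabilities in \[0, 1\].
#' @param criterion_k Consecutive correct choices required (default 6).
#' @param seed Integer seed.
#' @param max_trials Hard cap preventing unbounded sequences (default 1000).
#' @param p_omission Probability that a trial is an omission (default 0);
#'   omissions consume a trial without a choice.
#' @return List with `outcomes` (character vector) and `criterion_reached`.
#' @export
generate_trial_sequence <- function(p_correct_pre, p_correct_post,
                                    criterion_k = 6L, seed = 1L,
                                    max_trials = 1000L, p_omission = 0) {
  p_correct_pre <- check_prob(p_correct_pre, "p_correct_pre")
  p_correct_post <- check_prob(p_correct_post, "p_correct_post")
  p_omission <- check_prob(p_omission, "p_omission")
  criterion_k <- check_scalar_int(criterion_k, "criterion_k", 1L)
  max_trials <- check_scalar_int(max_trials, "max_trials", criterion_k)
  set.seed(check_scalar_int(seed, "seed", 0L))
  outcomes <- character(0)
  run <- 0L
  seen_correct <- FALSE
  while (length(outcomes) < max_trials) {
    if (p_omission > 0 && stats::runif(1) < p_omission) {
      outcomes <- c(outcomes, "omission")
      run <- 0L
      next
    }
    p <- if (seen_correct) p_correct_post else p_correct_pre
    ok <- stats::runif(1) < p
    outcomes <- c(outcomes, if (ok) "correct" else "error")
    if (ok) {
      seen_correct <- TRUE
      run <- run + 1L
      if (run == criterion_k) {
        return(list(outcomes = outcomes, criterion_reached = TRUE))
      }
    } else {
      run <- 0L
    }
  }
  list(outcomes = outcomes, criterion_reached = FALSE)
}

# Homogeneous-Poisson event times on [t0, t1) at `rate` events/s.
poisson_times <- function(rate, t0, t1) {
  k <- stats::rpois(1, rate * (t1 - t0))
  if (k == 0) return(numeric(0))
  sort(stats::runif(k, t0, t1))
}

#' Generate Pavlovian conditioned-approach event logs
#'
#' For each subject and session: `n_trials` trials, each a 30-s CS window
#' preceded by a variable inter-trial interval drawn uniform on 90-210 s.
#' Lever presses and receptacle entries arrive as homogeneous Poisson events
#' at the CS rates inside the CS window; baseline receptacle entries arrive
#' at `entry_rate_baseline` inside the 30-s pre-CS window. A sucrose delivery
#' is logged at each CS offset.
#'
#' @param design Design table.
#' @param press_rate_cs Lever presses per second during the CS (default
#'   0.10/s, i.e. 3 per trial on average).
#' @param entry_rate_cs Receptacle entries per second during the CS
#'   (default 0.15/s).
#' @param entry_rate_baseline Baseline receptacle entries per second in the
#'   pre-CS window (default 0.05/s).
#' @param n_trials Trials per session (default 15).
#' @param n_sessions Sessions per subject (default 20, i.e. 4 weeks of daily
#'   training).
#' @param seed Integer seed.
#' @param cs_duration_s CS duration (default 30 s).
#' @param iti_range_s Inter-trial-interval range (default 90-210 s).
#' @return Tibble with `subject_id`, `session`, `event_type`, `timestamp_s`,
#'   sorted within subject x session.
#' @export
generate_pavlovian_eventlog <- function(design, press_rate_cs = 0.10,
                                        entry_rate_cs = 0.15,
                                        entry_rate_baseline = 0.05,
                                        n_trials = 15L, n_sessions = 20L,
                                        seed = 1L, cs_duration_s = 30,
                                        iti_range_s = c(90, 210)) {
  rates <- c(press_rate_cs, entry_rate_cs, entry_rate_baseline)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop_flexconn("Event rates must be non-negative.",
                  class = "flexconn_validation_error")
  }
  n_trials <- check_scalar_int(n_trials, "n_trials", 1L)
  n_sessions <- check_scalar_int(n_sessions, "n_sessions", 1L)
  logs <- vector("list", nrow(design) * n_sessions)
  k <- 0L
  for (i in seq_len(nrow(design))) {
    set.seed(subject_seed(seed, i))
    for (s in seq_len(n_sessions)) {
      t <- 0
      ev_type <- character(0)
      ev_time <- numeric(0)
      add <- function(type, times) {
        if (length(times)) {
          ev_type <<- c(ev_type, rep(type, length(times)))
          ev_time <<- c(ev_time, times)
        }
      }
      for (tr in seq_len(n_trials)) {
        onset <- t + stats::runif(1, iti_range_s[1], iti_range_s[2])
        offset <- onset + cs_duration_s
        add("receptacle_entry",
            poisson_times(entry_rate_baseline, onset - cs_duration_s, onset))
        add("cs_onset", onset)
        add("lever_press", poisson_times(press_rate_cs, onset, offset))
        add("receptacle_entry", poisson_times(entry_rate_cs, onset, offset))
        add("cs_offset", offset)
        add("sucrose_delivery", offset)
        t <- offset
      }
      ord <- order(ev_time)
      k <- k + 1L
      logs[[k]] <- tibble::tibble(
        subject_id = design$subject_id[i], session = s,
        event_type = ev_type[ord], timestamp_s = ev_time[ord]
      )
    }
  }
  dplyr::bind_rows(logs)
}

#' Simulate a complete synthetic study
#'
#' Generates the design, the ROI time series with the planted connectivity
#' reduction, the per-subject connectivity matrices, the subnetwork mediator
#' (mean Fisher z over the planted edges, as computed by the connectivity
#' module - the mediation path is real, not assumed), the Poisson set-shift
#' error counts driven by that mediator, and optionally the Pavlovian event
#' logs.
#'
#' @param config A [synthetic_config()].
#' @param eventlog Also generate Pavlovian event logs? (default `FALSE`;
#'   they are the slowest component and independent of the imaging chain).
#' @param n_sessions Sessions per subject when `eventlog = TRUE`.
#' @return List of class `synthetic_study` with elements `design`,
#'   `timeseries`, `conn`, `mediator` (per-subject planted-subnetwork mean
#'   z), `counts`, `eventlog` (or `NULL`), `truth` (all planted parameters),
#'   `config`.
#' @export
simulate_study <- function(config = synthetic_config(), eventlog = FALSE,
                           n_sessions = 20L) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- generate_design(config$n_per_cell, config$seed)
  ts <- generate_roi_timeseries(design, config$network, config$n_timepoints,
                                seed = config$seed,
                                tr_seconds = config$tr_seconds,
                                ar1 = config$ar1)
  conn <- lapply(ts, connectivity_matrix)
  z <- edge_matrix(conn, "z")
  mediator <- rowMeans(z[, config$network$affected_edges, drop = FALSE])
  counts <- generate_setshift_counts(design, mediator, config$mediation,
                                     seed = config$seed + 1000L)
  log <- if (eventlog) {
    generate_pavlovian_eventlog(design, n_sessions = n_sessions,
                                seed = config$seed + 2000L)
  }
  structure(list(
    design = design, timeseries = ts, conn = conn, mediator = mediator,
    counts = counts, eventlog = log,
    truth = list(network = config$network, mediation = config$mediation,
                 reduced_corr = unclass(reduced_corr(config$network))),
    config = config
  ), class = "synthetic_study")
}
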