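# End-to-end orchestration: scoring -> GLM tables -> connectivity -> edge
# statistics / NBS -> edge-behavior correlation -> selection / PC1 ->
# mediation, from a single config, with seeds and a machine-readable report.

#' Pipeline configuration
#'
#' @param synthetic A [synthetic_config()] to generate inputs, or `NULL` to
#'   read from `input_dir`.
#' @param input_dir Directory with `design.csv`, `timeseries/`, `counts.csv`
#'   (and optionally `eventlog.csv`), as written by
#'   [write_synthetic_dataset()]. Ignored in synthetic mode.
#' @param supra_p NBS edge suprathreshold (default 0.05).
#' @param select_p Edge-selection threshold for the mediator subnetwork
#'   (default 0.1, uncorrected).
#' @param fdr_q FDR significance level for edge-behavior correlations
#'   (default 0.05).
#' @param criterion_k Set-shift criterion run length (default 6).
#' @param k_last_sessions Pavlovian summary window (default 5).
#' @param n_perm NBS permutations (default 5000).
#' @param n_boot Mediation bootstrap draws (default 1000).
#' @param seed Master seed for permutation and bootstrap stages.
#' @param nbs_variant `"link"` (default) or `"component"`.
#' @param outcome_phase Which set-shift phase supplies the outcome counts
#'   when reading trial-level files (default `"reversal2"`); synthetic mode
#'   generates the outcome counts directly.
#' @param clean Apply [clean_timeseries()] before correlation? Default
#'   `FALSE` in synthetic mode (generated signals are already white and
#'   confound-free) and `TRUE` for file inputs.
#' @param band_hz Band for cleaning (default 0.01-0.15 Hz).
#' @param include_interaction Exposure x mediator interaction in the
#'   mediation outcome model (default `FALSE`).
#' @param score_pavlovian Score event logs when present (default `TRUE`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_dir = NULL,
                            supra_p = 0.05, select_p = 0.1, fdr_q = 0.05,
                            criterion_k = 6L, k_last_sessions = 5L,
                            n_perm = 5000L, n_boot = 1000L, seed = 1L,
                            nbs_variant = c("link", "component"),
                            outcome_phase = "reversal2",
                            clean = is.null(synthetic),
                            band_hz = c(0.01, 0.15),
                            include_interaction = FALSE,
                            score_pavlovian = TRUE) {
  nbs_variant <- match.arg(nbs_variant)
  for (nm in c("supra_p", "fdr_q")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v > 1) {
      stop_flexconn(sprintf("`%s` must lie in (0, 1].", nm),
                    class = "flexconn_validation_error")
    }
  }
  if (!is.numeric(select_p) || select_p < 0 || select_p > 1) {
    stop_flexconn("`select_p` must lie in [0, 1].",
                  class = "flexconn_validation_error")
  }
  if (is.null(synthetic) && is.null(input_dir)) {
    stop_flexconn("Either a synthetic config or an input directory is required.")
  }
  structure(list(
    synthetic = synthetic, input_dir = input_dir,
    supra_p = supra_p, select_p = select_p, fdr_q = fdr_q,
    criterion_k = check_scalar_int(criterion_k, "criterion_k"),
    k_last_sessions = check_scalar_int(k_last_sessions, "k_last_sessions"),
    n_perm = check_scalar_int(n_perm, "n_perm", 100L),
    n_boot = check_scalar_int(n_boot, "n_boot", 200L),
    seed = check_scalar_int(seed, "seed", 0L),
    nbs_variant = nbs_variant,
    outcome_phase = outcome_phase,
    clean = isTRUE(clean), band_hz = band_hz,
    include_interaction = isTRUE(include_interaction),
    score_pavlovian = isTRUE(score_pavlovian)
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and returns a machine-readable report:
#' behavioral scoring (Pavlovian metrics and/or outcome counts), report-style
#' GLM tables, connectivity matrices, edgewise group statistics with NBS
#' family-wise error control, edge-behavior correlations (beta p + FDR),
#' subnetwork selection and PC1, and counterfactual mediation. All warnings
#' raised by stages are collected into the report. If no edges pass the
#' selection threshold the mediation stage is skipped with an explicit
#' warning and the run still succeeds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage artifacts are written
#'   as CSV/JSON (`design.csv`, `edges.csv`, `edge_stats.csv`,
#'   `behavior_corr.csv`, `nbs_result.json`, `subnetwork.json`,
#'   `mediation.json`, `pavlovian_metrics.csv`, `report.json`).
#' @return List of class `run_report` with per-stage results, a `warnings`
#'   character vector and a `provenance` block (config hash, seeds, package
#'   version).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sim <- collect(simulate_study(config$synthetic,
                                  eventlog = config$score_pavlovian,
                                  n_sessions = config$k_last_sessions + 1L))
    design <- sim$design
    ts <- sim$timeseries
    counts <- sim$counts
    eventlog <- sim$eventlog
  } else {
    design <- read_design(file.path(config$input_dir, "design.csv"))
    ts <- read_timeseries_dir(file.path(config$input_dir, "timeseries"),
                              design$subject_id)
    counts_path <- file.path(config$input_dir, "counts.csv")
    trials_path <- file.path(config$input_dir, "trials.csv")
    if (file.exists(counts_path)) {
      counts <- readr::read_csv(counts_path, show_col_types = FALSE)
    } else if (file.exists(trials_path)) {
      trials <- readr::read_csv(trials_path, show_col_types = FALSE)
      phase_scores <- score_phase_table(trials, config$criterion_k)
      sel <- phase_scores[phase_scores$phase == config$outcome_phase, ]
      counts <- tibble::tibble(subject_id = sel$subject_id,
                               count = sel$total_active_errors)
    } else {
      stop_flexconn(sprintf(
        "Stage 'behavior': neither %s nor %s exists.", counts_path,
        trials_path), class = "flexconn_missing_input")
    }
    counts <- counts[match(design$subject_id, counts$subject_id), ]
    log_path <- file.path(config$input_dir, "eventlog.csv")
    eventlog <- if (config$score_pavlovian && file.exists(log_path)) {
      readr::read_csv(log_path, show_col_types = FALSE)
    }
  }

  # --- behavioral scoring + report tables ---------------------------------
  pav_summary <- NULL
  pav_stats <- NULL
  if (!is.null(eventlog)) {
    pav_summary <- collect(summarize_pavlovian(eventlog,
                                               config$k_last_sessions))
    pav_summary <- pav_summary[match(design$subject_id,
                                     pav_summary$subject_id), ]
    count_metrics <- c("lever_presses", "receptacle_entries")
    pav_stats <- dplyr::bind_rows(lapply(count_metrics, function(mname) {
      tb <- collect(glm_effects_table(round(pav_summary[[mname]]),
                                      design$exposure, design$sex))
      tb$variable <- mname
      tb
    }))
    elev <- collect(two_way_anova(pav_summary$elevation_score,
                                  design$exposure, design$sex,
                                  effect_names = c("exposure", "sex",
                                                   "interaction")))
    elev$variable <- "elevation_score"
    pav_stats <- list(glm = pav_stats, elevation_anova = elev)
  }
  outcome_stats <- collect(glm_effects_table(counts$count, design$exposure,
                                             design$sex))

  # --- connectivity -------------------------------------------------------
  if (config$clean) {
    ts <- collect(lapply(ts, clean_timeseries, band_hz = config$band_hz))
  }
  conn <- collect(lapply(ts, connectivity_matrix))
  z <- edge_matrix(conn, "z")
  edges_tbl <- edges_long(conn)

  # --- edgewise statistics + NBS ------------------------------------------
  edge_stats <- collect(edgewise_group_stats(z, design))
  nbs <- collect(nbs_fwe(z, design$exposure, supra_p = config$supra_p,
                         n_perm = config$n_perm, seed = config$seed,
                         variant = config$nbs_variant,
                         edges = edge_table(conn[[1]]$roi_names)))

  # --- edge-behavior correlation ------------------------------------------
  behavior_corr <- collect(edge_behavior_correlation(z, counts$count, design))

  # --- subnetwork + mediation ---------------------------------------------
  selected <- if (config$select_p > 0) {
    select_edges(edge_stats, config$select_p, "exposure")
  } else {
    character(0)
  }
  subnetwork <- NULL
  mediation <- NULL
  if (length(selected) < 2) {
    note(sprintf(
      "Mediation stage skipped: no edges selected at p < %g (%d found).",
      config$select_p, length(selected)))
  } else {
    subnetwork <- collect(subnetwork_pc1(z[, selected, drop = FALSE]))
    mediation <- collect(causal_mediation(
      x = design$exposure, m = subnetwork$scores, y = counts$count,
      covariate = design$sex,
      include_interaction = config$include_interaction,
      n_boot = config$n_boot, seed = config$seed
    ))
  }

  provenance <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_perm = config$n_perm,
    n_boot = config$n_boot,
    package_version = as.character(utils::packageVersion("flexconn"))
  )
  report <- structure(list(
    design = design,
    pavlovian_summary = pav_summary,
    pavlovian_stats = pav_stats,
    outcome_stats = outcome_stats,
    counts = counts,
    edges = edges_tbl,
    edge_stats = edge_stats,
    nbs = nbs,
    behavior_corr = behavior_corr,
    selected_edges = selected,
    subnetwork = subnetwork,
    mediation = mediation,
    warnings = warnings_log,
    provenance = provenance
  ), class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  %d subjects, %d edges\n", nrow(x$design),
              length(unique(x$edges$edge))))
  sig <- x$nbs$table$edge[x$nbs$table$significant]
  cat(sprintf("  NBS significant edges: %s\n",
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  cat(sprintf("  selected edges (subnetwork): %d\n", length(x$selected_edges)))
  if (!is.null(x$subnetwork)) {
    cat(sprintf("  PC1 variance explained: %.1f%%\n",
                100 * x$subnetwork$variance_explained))
  }
  if (!is.null(x$mediation)) {
    cat(sprintf("  proportion mediated (log scale): %.1f%% [p_indirect = %.4g]\n",
                100 * x$mediation$pm_log, x$mediation$p_indirect))
  }
  if (length(x$warnings)) {
    cat(sprintf("  warnings collected: %d\n", length(x$warnings)))
  }
  invisible(x)
}

#' Write a run report's stage artifacts to disk
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$design, file.path(out_dir, "design.csv"))
  readr::write_csv(report$edges, file.path(out_dir, "edges.csv"))
  readr::write_csv(report$edge_stats, file.path(out_dir, "edge_stats.csv"))
  readr::write_csv(report$behavior_corr,
                   file.path(out_dir, "behavior_corr.csv"))
  if (!is.null(report$pavlovian_summary)) {
    readr::write_csv(report$pavlovian_summary,
                     file.path(out_dir, "pavlovian_metrics.csv"))
  }
  nbs <- report$nbs
  jsonlite::write_json(
    list(variant = nbs$variant, n_perm = nbs$n_perm,
         exhaustive = nbs$exhaustive, seed = nbs$seed,
         supra_p = nbs$supra_p,
         null_max_stat = as.list(round(unclass(nbs$null_max_stat), 6)),
         table = nbs$table),
    file.path(out_dir, "nbs_result.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$subnetwork)) {
    sn <- report$subnetwork
    jsonlite::write_json(
      list(edges = sn$edges, weights = unname(sn$weights),
           variance_explained = sn$variance_explained,
           scores = as.list(sn$scores)),
      file.path(out_dir, "subnetwork.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$mediation)) {
    m <- report$mediation
    jsonlite::write_json(
      list(rr_nde = m$rr_nde, rr_nie = m$rr_nie, rr_total = m$rr_total,
           pm_log = m$pm_log, pm_excess_rr = m$pm_excess_rr,
           p_indirect = m$p_indirect, ci = m$ci,
           inconsistent = m$inconsistent, settings = m$settings),
      file.path(out_dir, "mediation.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(provenance = report$provenance, warnings = report$warnings,
         selected_edges = report$selected_edges),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
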