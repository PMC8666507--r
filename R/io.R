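# Plain-text readers/writers for the pipeline's stage artifacts. All
# intermediates are CSV or JSON so any stage can be inspected or replaced.

#' Write a synthetic study to disk as plain-text artifacts
#'
#' Writes `design.csv`, one `timeseries/<subject_id>.csv` per subject
#' (header = ROI names, one row per time point), `counts.csv`,
#' `eventlog.csv` (when present) and `truth.json` (all planted parameters
#' and the repaired exposure-group correlation matrix).
#'
#' @param sim A `synthetic_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_study"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(sim$design, file.path(dir, "design.csv"))
  readr::write_csv(sim$counts, file.path(dir, "counts.csv"))
  if (!is.null(sim$eventlog)) {
    readr::write_csv(sim$eventlog, file.path(dir, "eventlog.csv"))
  }
  for (id in names(sim$timeseries)) {
    readr::write_csv(
      tibble::as_tibble(sim$timeseries[[id]]$data),
      file.path(dir, "timeseries", paste0(id, ".csv"))
    )
  }
  net <- sim$config$network
  med <- sim$config$mediation
  truth <- list(
    roi_names = net$roi_names,
    affected_edges = net$affected_edges,
    delta = net$delta,
    base_corr = net$base_corr,
    reduced_corr = sim$truth$reduced_corr,
    mediation = unclass(med),
    n_per_cell = sim$config$n_per_cell,
    n_timepoints = sim$config$n_timepoints,
    tr_seconds = sim$config$tr_seconds,
    seed = sim$config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Read a design table from CSV
#'
#' @param path Path to a `design.csv` with columns `subject_id`, `sex`,
#'   `exposure`.
#' @return Tibble design table.
#' @export
read_design <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("subject_id", "sex", "exposure")
  if (!all(req %in% names(d))) {
    stop_flexconn(sprintf("Design file %s must have columns %s.", path,
                          paste(req, collapse = ", ")))
  }
  if (anyDuplicated(d$subject_id)) {
    stop_flexconn("Duplicate subject ids in design table.",
                  class = "flexconn_validation_error")
  }
  d
}

#' Read per-subject ROI time-series CSVs
#'
#' @param dir Directory containing `<subject_id>.csv` files (header = ROI
#'   names, one row per time point).
#' @param subject_ids Subjects to read, in order.
#' @param tr_seconds Sampling interval to attach.
#' @return Named list of [roi_timeseries()] objects.
#' @export
read_timeseries_dir <- function(dir, subject_ids, tr_seconds = 2) {
  out <- lapply(subject_ids, function(id) {
    path <- file.path(dir, paste0(id, ".csv"))
    if (!file.exists(path)) {
      stop_flexconn(sprintf("Missing time-series file for subject %s: %s",
                            id, path), class = "flexconn_missing_input")
    }
    d <- readr::read_csv(path, show_col_types = FALSE)
    roi_timeseries(as.matrix(d), names(d), tr_seconds, id)
  })
  stats::setNames(out, subject_ids)
}
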