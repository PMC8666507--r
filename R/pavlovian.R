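# Pavlovian conditioned-approach scoring: timestamped session logs ->
# per-session conditioned-approach metrics -> per-subject summaries.

PAVLOVIAN_EVENTS <- c("cs_onset", "cs_offset", "lever_press",
                      "receptacle_entry", "sucrose_delivery")

#' Score one Pavlovian session log into conditioned-approach metrics
#'
#' Tallies lever presses and receptacle entries inside each 30-s CS window
#' `[onset, onset + 30)`, latencies from CS onset to the first response in
#' the trial (censored at the CS duration on no-response trials), response
#' probabilities as the fraction of trials with at least one response, and
#' the elevation score: receptacle entries during the CS minus entries in the
#' 30 s immediately preceding it, summed over trials.
#'
#' @param log Data frame for a single subject x session with columns
#'   `event_type` (one of `cs_onset`, `cs_offset`, `lever_press`,
#'   `receptacle_entry`, `sucrose_delivery`) and `timestamp_s`.
#' @param cs_duration_s CS window length in seconds (default 30).
#' @param latency_mode `"censor"` (default) includes no-response trials at
#'   the censoring bound in the mean latency; `"exclude"` drops them.
#' @return One-row tibble with `lever_presses`, `lever_latency_s`,
#'   `lever_probability`, `receptacle_entries`, `receptacle_latency_s`,
#'   `receptacle_probability`, `elevation_score`, `n_trials`.
#' @export
score_session <- function(log, cs_duration_s = 30,
                          latency_mode = c("censor", "exclude")) {
  latency_mode <- match.arg(latency_mode)
  if (!all(c("event_type", "timestamp_s") %in% names(log))) {
    stop_flexconn("`log` needs columns event_type and timestamp_s.")
  }
  bad <- setdiff(unique(log$event_type), PAVLOVIAN_EVENTS)
  if (length(bad)) {
    stop_flexconn(sprintf("Unknown event type(s): %s.", paste(bad, collapse = ", ")),
                  class = "flexconn_validation_error")
  }
  onsets <- sort(log$timestamp_s[log$event_type == "cs_onset"])
  n_trials <- length(onsets)
  if (n_trials == 0) {
    stop_flexconn("Session log contains no cs_onset events.",
                  class = "flexconn_validation_error")
  }
  if (any(diff(onsets) < 2 * cs_duration_s)) {
    stop_flexconn("CS windows overlap their neighbours' pre-CS windows.",
                  class = "flexconn_validation_error")
  }
  if (onsets[1] - cs_duration_s < 0) {
    stop_flexconn("Pre-CS window of the first trial precedes session start.",
                  class = "flexconn_validation_error")
  }
  presses <- sort(log$timestamp_s[log$event_type == "lever_press"])
  entries <- sort(log$timestamp_s[log$event_type == "receptacle_entry"])

  per_trial <- function(times, onset) {
    times[times >= onset & times < onset + cs_duration_s] - onset
  }
  trial_stats <- lapply(onsets, function(on) {
    pr <- per_trial(presses, on)
    en <- per_trial(entries, on)
    pre_en <- sum(entries >= on - cs_duration_s & entries < on)
    list(
      n_press = length(pr), n_entry = length(en),
      lat_press = if (length(pr)) min(pr) else NA_real_,
      lat_entry = if (length(en)) min(en) else NA_real_,
      elevation = length(en) - pre_en
    )
  })
  get <- function(f) vapply(trial_stats, `[[`, numeric(1), f)
  mean_latency <- function(lat) {
    if (latency_mode == "censor") {
      mean(ifelse(is.na(lat), cs_duration_s, lat))
    } else {
      if (all(is.na(lat))) cs_duration_s else mean(lat, na.rm = TRUE)
    }
  }
  tibble::tibble(
    lever_presses = sum(get("n_press")),
    lever_latency_s = mean_latency(get("lat_press")),
    lever_probability = mean(get("n_press") > 0),
    receptacle_entries = sum(get("n_entry")),
    receptacle_latency_s = mean_latency(get("lat_entry")),
    receptacle_probability = mean(get("n_entry") > 0),
    elevation_score = sum(get("elevation")),
    n_trials = n_trials
  )
}

#' Score a full event log (all subjects and sessions)
#'
#' @param eventlog Data frame with columns `subject_id`, `session`,
#'   `event_type`, `timestamp_s`.
#' @inheritParams score_session
#' @return Tibble, one row of metrics per subject x session.
#' @export
score_eventlog <- function(eventlog, cs_duration_s = 30,
                           latency_mode = c("censor", "exclude")) {
  latency_mode <- match.arg(latency_mode)
  req <- c("subject_id", "session", "event_type", "timestamp_s")
  if (!all(req %in% names(eventlog))) {
    stop_flexconn(sprintf("`eventlog` must have columns %s.",
                          paste(req, collapse = ", ")))
  }
  eventlog |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::reframe(score_session(
      data.frame(event_type = .data$event_type, timestamp_s = .data$timestamp_s),
      cs_duration_s = cs_duration_s, latency_mode = latency_mode
    )) |>
    tibble::as_tibble()
}

#' Summarize a subject's conditioned approach over the last k sessions
#'
#' Arithmetic mean of each metric over the final `k_last` sessions in
#' session-index order (the training-endpoint summary used for group
#' statistics).
#'
#' @param sessions Tibble of per-session metrics (as from [score_session()]
#'   or [score_eventlog()] for one subject) with a `session` column or in
#'   session order.
#' @param k_last Number of final sessions to average (default 5).
#' @return One-row tibble of averaged metrics.
#' @export
summarize_subject <- function(sessions, k_last = 5L) {
  k_last <- check_scalar_int(k_last, "k_last", min = 1L)
  if (nrow(sessions) < k_last) {
    stop_flexconn(sprintf("Need at least %d sessions, got %d.",
                          k_last, nrow(sessions)),
                  class = "flexconn_validation_error")
  }
  if ("session" %in% names(sessions)) {
    sessions <- sessions[order(sessions$session), , drop = FALSE]
  }
  metric_cols <- intersect(
    c("lever_presses", "lever_latency_s", "lever_probability",
      "receptacle_entries", "receptacle_latency_s", "receptacle_probability",
      "elevation_score"),
    names(sessions)
  )
  lastk <- utils::tail(sessions, k_last)
  tibble::as_tibble(as.list(colMeans(lastk[metric_cols])))
}

#' Per-subject conditioned-approach summary table
#'
#' @param eventlog Full event log (all subjects/sessions).
#' @param k_last Final sessions to average (default 5).
#' @inheritParams score_session
#' @return Tibble, one row per subject.
#' @export
summarize_pavlovian <- function(eventlog, k_last = 5L, cs_duration_s = 30,
                                latency_mode = c("censor", "exclude")) {
  latency_mode <- match.arg(latency_mode)
  per_session <- score_eventlog(eventlog, cs_duration_s, latency_mode)
  per_session |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::reframe(summarize_subject(dplyr::pick(dplyr::everything()), k_last)) |>
    tibble::as_tibble()
}
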