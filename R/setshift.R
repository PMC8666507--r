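# Attentional set-shift scoring: criterion detection and the prepotent /
# regressive error taxonomy. Outcomes are the 3-symbol alphabet
# "correct" / "error" / "omission".

SETSHIFT_PHASES <- c("acquisition", "reacq1", "reversal1", "reacq2",
                     "reversal2", "reacq3", "ed_shift")

check_outcomes <- function(outcomes) {
  outcomes <- as.character(outcomes)
  if (length(outcomes) == 0) {
    stop_flexconn("Trial sequence is empty.", class = "flexconn_validation_error")
  }
  bad <- setdiff(unique(outcomes), c("correct", "error", "omission"))
  if (length(bad)) {
    stop_flexconn(sprintf("Unknown trial outcome(s): %s.",
                          paste(bad, collapse = ", ")),
                  class = "flexconn_validation_error")
  }
  outcomes
}

#' Trials to criterion (first run of k consecutive correct choices)
#'
#' Returns the 1-based count of trials consumed up to and including the trial
#' that completes the first run of `criterion_k` consecutive correct choices.
#' Both errors and omissions break the run (an omitted trial counts against
#' the criterion). If no such run occurs, `NA` is returned with the
#' `criterion_reached` attribute set to `FALSE`.
#'
#' @param outcomes Character vector of `"correct"`, `"error"`, `"omission"`.
#' @param criterion_k Run length required (default 6 consecutive correct).
#' @return Integer trial count, or `NA` if the criterion was never reached;
#'   attribute `criterion_reached` carries the flag.
#' @export
#' @examples
#' trials_to_criterion(rep("correct", 6))          # 6
#' trials_to_criterion(c("error", rep("correct", 6)))  # 7
trials_to_criterion <- function(outcomes, criterion_k = 6L) {
  outcomes <- check_outcomes(outcomes)
  criterion_k <- check_scalar_int(criterion_k, "criterion_k", min = 1L)
  run <- 0L
  for (i in seq_along(outcomes)) {
    run <- if (outcomes[i] == "correct") run + 1L else 0L
    if (run == criterion_k) {
      return(structure(i, criterion_reached = TRUE))
    }
  }
  structure(NA_integer_, criterion_reached = FALSE)
}

#' Classify set-shift errors into the prepotent / regressive taxonomy
#'
#' Errors committed strictly before the first correct choice in the phase are
#' prepotent (perseveration on the previously reinforced contingency). Every
#' later error is regressive: *initial* if the immediately preceding
#' non-omission outcome was correct, *subsequent* if it was itself an error.
#' Omissions are tallied separately and never count as active errors; because
#' an omitted trial carries no feedback, it is skipped when determining the
#' preceding outcome (configurable via `skip_omissions`).
#'
#' @param outcomes Character vector of trial outcomes.
#' @param skip_omissions Should omissions be skipped when finding the
#'   preceding outcome for the initial/subsequent split? Default `TRUE`.
#' @return A list of class `phase_score` with counts `prepotent`,
#'   `regressive_initial`, `regressive_subsequent`, `total_active_errors`,
#'   `omissions`, `n_correct`, `n_trials`.
#' @export
#' @examples
#' classify_errors(c("error", "error", "correct", "error", "error",
#'                   rep("correct", 6)))
classify_errors <- function(outcomes, skip_omissions = TRUE) {
  outcomes <- check_outcomes(outcomes)
  prepotent <- 0L
  reg_initial <- 0L
  reg_subsequent <- 0L
  seen_correct <- FALSE
  last_choice <- NA_character_  # last non-omission outcome
  for (o in outcomes) {
    if (o == "omission") {
      if (!skip_omissions) last_choice <- o
      next
    }
    if (o == "error") {
      if (!seen_correct) {
        prepotent <- prepotent + 1L
      } else if (identical(last_choice, "correct")) {
        reg_initial <- reg_initial + 1L
      } else {
        reg_subsequent <- reg_subsequent + 1L
      }
    } else {
      seen_correct <- TRUE
    }
    last_choice <- o
  }
  structure(list(
    prepotent = prepotent,
    regressive_initial = reg_initial,
    regressive_subsequent = reg_subsequent,
    total_active_errors = prepotent + reg_initial + reg_subsequent,
    omissions = sum(outcomes == "omission"),
    n_correct = sum(outcomes == "correct"),
    n_trials = length(outcomes)
  ), class = "phase_score")
}

#' Score a single set-shift phase
#'
#' Combines [trials_to_criterion()] and [classify_errors()] into one row.
#'
#' @inheritParams classify_errors
#' @inheritParams trials_to_criterion
#' @return One-row tibble with criterion and error-taxonomy counts.
#' @export
score_phase <- function(outcomes, criterion_k = 6L, skip_omissions = TRUE) {
  ttc <- trials_to_criterion(outcomes, criterion_k)
  cls <- classify_errors(outcomes, skip_omissions)
  tibble::tibble(
    trials_to_criterion = as.integer(ttc),
    criterion_reached = attr(ttc, "criterion_reached"),
    prepotent = cls$prepotent,
    regressive_initial = cls$regressive_initial,
    regressive_subsequent = cls$regressive_subsequent,
    total_active_errors = cls$total_active_errors,
    omissions = cls$omissions,
    n_trials = cls$n_trials
  )
}

#' Score a trial table into per-phase rows
#'
#' Takes a tidy trial-level table (one row per trial) and returns one row of
#' phase scores per subject x phase, ready for the GLM stage.
#'
#' @param trials Data frame with columns `subject_id`, `phase`,
#'   `trial_index`, `outcome`. Trials are ordered by `trial_index` within
#'   each subject x phase.
#' @param criterion_k Consecutive correct choices required (default 6).
#' @param skip_omissions Passed to [classify_errors()].
#' @return Tibble, one row per subject x phase.
#' @export
score_phase_table <- function(trials, criterion_k = 6L, skip_omissions = TRUE) {
  req <- c("subject_id", "phase", "trial_index", "outcome")
  if (!all(req %in% names(trials))) {
    stop_flexconn(sprintf("`trials` must have columns %s.",
                          paste(req, collapse = ", ")))
  }
  dup <- trials |>
    dplyr::count(.data$subject_id, .data$phase, .data$trial_index) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop_flexconn("Duplicate subject x phase x trial_index rows.",
                  class = "flexconn_validation_error")
  }
  trials |>
    dplyr::arrange(.data$subject_id, .data$phase, .data$trial_index) |>
    dplyr::group_by(.data$subject_id, .data$phase) |>
    dplyr::reframe(score_phase(.data$outcome, criterion_k, skip_omissions)) |>
    tibble::as_tibble()
}
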