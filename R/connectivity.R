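# ROI time-series cleaning (confound regression + zero-phase band-pass) and
# Pearson / Fisher-z connectivity matrices.

#' Construct an ROI time-series object
#'
#' @param data Numeric T x R matrix; rows are time points, columns ROIs.
#' @param roi_names Unique ROI labels, one per column.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param subject_id Optional subject label.
#' @return Object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, roi_names = colnames(data), tr_seconds = 2,
                           subject_id = NA_character_) {
  data <- as.matrix(data)
  if (is.null(roi_names)) {
    stop_flexconn("ROI names are required.", class = "flexconn_validation_error")
  }
  if (anyDuplicated(roi_names)) {
    stop_flexconn("ROI names must be unique.", class = "flexconn_validation_error")
  }
  if (length(roi_names) != ncol(data)) {
    stop_flexconn("One ROI name per column is required.")
  }
  if (any(!is.finite(data))) {
    stop_flexconn("Time series contain missing or non-finite values.",
                  class = "flexconn_validation_error")
  }
  if (nrow(data) <= ncol(data)) {
    stop_flexconn(sprintf(
      "Need more time points (%d) than ROIs (%d).", nrow(data), ncol(data)),
      class = "flexconn_validation_error")
  }
  colnames(data) <- roi_names
  structure(list(subject_id = subject_id, roi_names = roi_names,
                 data = data, tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s: %d time points x %d ROIs (TR %gs)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

# Zero-phase 4th-order Butterworth band-pass with reflective padding.
bandpass_filtfilt <- function(x, band_hz, tr_seconds, order = 4L) {
  fs <- 1 / tr_seconds
  nyq <- fs / 2
  if (band_hz[1] < 0 || band_hz[1] >= band_hz[2] || band_hz[2] >= nyq) {
    stop_flexconn(sprintf(
      "Band [%g, %g] Hz must satisfy 0 <= low < high < Nyquist (%g Hz).",
      band_hz[1], band_hz[2], nyq), class = "flexconn_validation_error")
  }
  bf <- signal::butter(order, band_hz / nyq, type = "pass")
  n <- length(x)
  pad <- min(n - 1L, 200L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]),        # reflect about the endpoints
          x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}

#' Clean ROI time series: confound regression then band-pass filtering
#'
#' Each ROI signal is replaced by its least-squares residual after projecting
#' out the confound columns (plus an intercept), then band-pass filtered with
#' a zero-phase forward-backward 4th-order Butterworth filter (reflective
#' padding). The default band 0.01-0.15 Hz is the resting-state band at a
#' 2-s repetition time (Nyquist 0.25 Hz). Rank-deficient confound sets are
#' reduced by dropping collinear columns with a warning.
#'
#' @param ts An [roi_timeseries()] object.
#' @param confounds Optional T x K numeric matrix of nuisance regressors
#'   (e.g., six rigid-motion parameters). `NULL` regresses out the intercept
#'   only.
#' @param band_hz Length-2 numeric `[low, high]` in Hz; `NULL` skips
#'   filtering.
#' @param order Butterworth order per pass (default 4).
#' @return A cleaned `roi_timeseries` object.
#' @export
clean_timeseries <- function(ts, confounds = NULL, band_hz = c(0.01, 0.15),
                             order = 4L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- ts$data
  n <- nrow(X)
  C <- cbind(intercept = rep(1, n))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) {
      stop_flexconn("Confounds must have one row per time point.")
    }
    C <- cbind(C, confounds)
    qrC <- qr(C)
    if (qrC$rank < ncol(C)) {
      keep <- qrC$pivot[seq_len(qrC$rank)]
      rlang::warn(sprintf(
        "Confound matrix is rank deficient; dropping %d collinear column(s).",
        ncol(C) - qrC$rank))
      C <- C[, sort(keep), drop = FALSE]
    }
  }
  resid <- stats::lm.fit(C, X)$residuals
  if (!is.null(band_hz)) {
    resid <- apply(resid, 2, bandpass_filtfilt, band_hz = band_hz,
                   tr_seconds = ts$tr_seconds, order = order)
  }
  roi_timeseries(resid, ts$roi_names, ts$tr_seconds, ts$subject_id)
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)` with clamping of `|r| = 1` to `1 - 1e-7` so degenerate
#' correlations stay finite; clamping emits a warning.
#'
#' @param r Correlation value(s) in \[-1, 1\].
#' @param eps Clamp margin (default 1e-7).
#' @return Fisher z value(s).
#' @export
#' @examples
#' fisher_z(0.5)  # atanh(0.5) = 0.5493061
fisher_z <- function(r, eps = 1e-7) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop_flexconn("`r` must lie in [-1, 1].", class = "flexconn_validation_error")
  }
  clamped <- abs(r) > 1 - eps
  if (any(clamped)) {
    rlang::warn(sprintf("%d correlation(s) at |r| ~ 1 clamped before atanh.",
                        sum(clamped)), class = "flexconn_clamp_warning")
  }
  atanh(pmin(1 - eps, pmax(-1 + eps, r)))
}

#' Pearson / Fisher-z connectivity matrix for one subject
#'
#' Pairwise Pearson correlations between ROI signals, plus the Fisher
#' z-transformed matrix used for group statistics (diagonal masked as `NA`).
#'
#' @param ts An [roi_timeseries()] object.
#' @return Object of class `connectivity_matrix`: list with `subject_id`,
#'   `roi_names`, `r` (R x R, unit diagonal), `z` (R x R, `NA` diagonal).
#' @export
connectivity_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$data, 2, stats::sd)
  if (any(sds == 0)) {
    stop_flexconn(sprintf("Zero-variance ROI signal: %s.",
                          paste(ts$roi_names[sds == 0], collapse = ", ")),
                  class = "flexconn_degenerate_error")
  }
  r <- stats::cor(ts$data)
  z <- r
  diag(z) <- 0
  z[] <- fisher_z(as.vector(z))
  diag(z) <- NA_real_
  structure(list(subject_id = ts$subject_id, roi_names = ts$roi_names,
                 r = r, z = z),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> subject %s: %d ROIs, %d edges\n",
              x$subject_id, length(x$roi_names),
              choose(length(x$roi_names), 2)))
  invisible(x)
}

#' Stack per-subject connectivity matrices into a subjects x edges z matrix
#'
#' @param conn_list List of [connectivity_matrix()] objects sharing an ROI set.
#' @param value `"z"` (default) or `"r"`.
#' @return Numeric matrix, one row per subject (named by `subject_id`), one
#'   column per canonical edge.
#' @export
edge_matrix <- function(conn_list, value = c("z", "r")) {
  value <- match.arg(value)
  if (!length(conn_list)) stop_flexconn("No connectivity matrices supplied.")
  roi_names <- conn_list[[1]]$roi_names
  edges <- edge_table(roi_names)
  rows <- lapply(conn_list, function(cm) {
    if (!identical(cm$roi_names, roi_names)) {
      stop_flexconn("All subjects must share the same ROI set and order.")
    }
    edge_values(cm[[value]], edges)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- unname(vapply(conn_list,
                                 function(cm) as.character(cm$subject_id),
                                 character(1)))
  out
}

#' Long-format edge table across subjects
#'
#' @inheritParams edge_matrix
#' @return Tibble with columns `subject_id`, `edge`, `r`, `z`.
#' @export
edges_long <- function(conn_list) {
  r <- edge_matrix(conn_list, "r")
  z <- edge_matrix(conn_list, "z")
  tibble::tibble(
    subject_id = rep(rownames(r), times = ncol(r)),
    edge = rep(colnames(r), each = nrow(r)),
    r = as.vector(r),
    z = as.vector(z)
  )
}
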