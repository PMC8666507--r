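#' Canonical ROI set
#'
#' The eight regions of interest used throughout the pipeline, in their fixed
#' canonical order: prelimbic cortex (PrL), infralimbic cortex (IL),
#' orbitofrontal cortex (OFC), primary somatosensory cortex (S1), nucleus
#' accumbens (NAc), caudate putamen (CPu), dorsal hippocampus (HippD) and
#' thalamus (Thal). All edge naming follows this order.
#'
#' @return Character vector of eight ROI labels.
#' @export
#' @examples
#' default_rois()
default_rois <- function() {
  c("PrL", "IL", "OFC", "S1", "NAc", "CPu", "HippD", "Thal")
}

#' Enumerate unordered ROI pairs (edges) in canonical order
#'
#' Edges are the upper triangle of the ROI x ROI matrix, ordered row-major by
#' (i, j) with i < j in the given ROI order, and named `"A-B"` with A before B
#' in that order. For 8 ROIs this yields the 28 canonical edges.
#'
#' @param roi_names Character vector of unique ROI labels.
#' @return A tibble with columns `edge`, `roi_a`, `roi_b`, `i`, `j`.
#' @export
#' @examples
#' edge_table(c("PrL", "NAc", "CPu"))
edge_table <- function(roi_names = default_rois()) {
  if (anyDuplicated(roi_names)) {
    stop_flexconn("ROI names must be unique.", class = "flexconn_validation_error")
  }
  R <- length(roi_names)
  if (R < 2) stop_flexconn("Need at least two ROIs to form edges.")
  idx <- which(upper.tri(diag(R)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble::tibble(
    edge  = paste0(roi_names[idx[, "row"]], "-", roi_names[idx[, "col"]]),
    roi_a = roi_names[idx[, "row"]],
    roi_b = roi_names[idx[, "col"]],
    i     = as.integer(idx[, "row"]),
    j     = as.integer(idx[, "col"])
  )
}

#' Normalize edge labels to canonical orientation
#'
#' Accepts `"A-B"` labels in either orientation and returns them with the
#' ROI that comes first in `roi_names` listed first.
#'
#' @param edges Character vector of `"A-B"` labels.
#' @param roi_names ROI ordering that defines the canonical orientation.
#' @return Character vector of canonical edge labels.
#' @export
canonical_edges <- function(edges, roi_names = default_rois()) {
  vapply(edges, function(e) {
    parts <- strsplit(e, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% roi_names)) {
      stop_flexconn(sprintf("Edge '%s' does not name two known ROIs.", e),
                    class = "flexconn_validation_error")
    }
    ord <- order(match(parts, roi_names))
    paste(parts[ord], collapse = "-")
  }, character(1), USE.NAMES = FALSE)
}

# Extract upper-triangle edge values of a symmetric matrix, canonical order.
edge_values <- function(mat, edges = NULL) {
  if (is.null(edges)) edges <- edge_table(rownames(mat) %||% colnames(mat))
  vals <- mat[cbind(edges$i, edges$j)]
  names(vals) <- edges$edge
  vals
}

`%||%` <- function(a, b) if (is.null(a)) b else a
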