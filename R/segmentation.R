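#' Extract the body region by thresholding and labeling
#'
#' Thresholds the SUV volume (default 0.5), labels 3D connected components
#' with full 26-connectivity, and keeps the component of maximum volume,
#' discarding noise and high accumulations outside the body.
#'
#' @param volume an [suv_volume].
#' @param threshold SUV threshold; voxels strictly above it are candidates.
#' @return A `binary_mask` of the body.
#' @export
extract_body_mask <- function(volume, threshold = 0.5) {
  m <- volume$data > threshold
  if (!any(m))
    stop("no voxel above SUV ", threshold, ": empty body", call. = FALSE)
  L <- label_components(m)
  sizes <- tabulate(L[L > 0L])
  binary_mask(L == which.max(sizes), spacing = volume$spacing)
}

# qualify 2D regions of a coronal (x, z) slice: threshold, label, keep
# regions passing size and centroid-window tests; returns logical slice
.coronal_candidates <- function(slice_suv, thr, min_size, x_win, z_win,
                                largest_only = FALSE) {
  m <- slice_suv > thr
  if (!any(m)) return(NULL)
  L <- label_components(m)
  sizes <- tabulate(L[L > 0L])
  keep <- matrix(FALSE, nrow(m), ncol(m))
  best <- 0L; best_size <- 0L
  for (lab in which(sizes >= min_size)) {
    w <- which(L == lab, arr.ind = TRUE)
    cx <- mean(w[, 1]); cz <- mean(w[, 2])
    if (cx >= x_win[1] && cx <= x_win[2] && cz >= z_win[1] && cz <= z_win[2]) {
      if (largest_only) {
        if (sizes[lab] > best_size) { best <- lab; best_size <- sizes[lab] }
      } else keep <- keep | (L == lab)
    }
  }
  if (largest_only && best > 0L) keep <- L == best
  if (!any(keep)) NULL else keep
}

#' Segment the bladder
#'
#' Tracer excreted in urine makes the bladder far hotter than soft tissue,
#' so a per-coronal-plane thresholding and 2D labeling pass extracts it.
#' Candidate regions must exceed an adaptive threshold (the larger of an
#' absolute SUV and a multiple of the soft-tissue median), have their
#' centroid in the inferior portion of the torso cuboid and the medial
#' portion of the AC span; the largest 3D connected union of candidates is
#' the bladder.
#'
#' @param volume an [suv_volume].
#' @param body the body `binary_mask`.
#' @param planes list with the physique planes `ns_z`, `th_z`, `ac_left_x`,
#'   `ac_right_x` (detected before organ registration).
#' @param config a [pet_config].
#' @return A `binary_mask`; errors with class `bladder_not_found` when no
#'   candidate region exists (callers may fall back to a fixed fraction of
#'   the TH-NS span).
#' @export
segment_bladder <- function(volume, body, planes, config = pet_config()) {
  if (!any(body$data)) stop("empty body mask", call. = FALSE)
  p <- config$bladder
  med <- stats::median(volume$data[body$data])
  thr <- max(p$threshold_abs, p$threshold_rel * med)
  span <- planes$ns_z - planes$th_z
  z_win <- c(planes$th_z, planes$th_z + p$z_frac * span)
  acw <- planes$ac_right_x - planes$ac_left_x
  xmid <- (planes$ac_left_x + planes$ac_right_x) / 2
  x_win <- xmid + c(-0.5, 0.5) * p$x_frac * acw
  d <- dim(volume$data)
  cand <- array(FALSE, d)
  for (y in seq_len(d[2])) {
    k <- .coronal_candidates(volume$data[, y, ], thr, p$min_size_2d,
                             x_win, z_win)
    if (!is.null(k)) cand[, y, ] <- k
  }
  cand <- cand & body$data
  if (!any(cand)) {
    cnd <- simpleError("no bladder candidate region above threshold")
    class(cnd) <- c("bladder_not_found", class(cnd))
    stop(cnd)
  }
  L <- label_components(cand)
  sizes <- tabulate(L[L > 0L])
  binary_mask(L == which.max(sizes), spacing = volume$spacing)
}

#' Segment the liver
#'
#' The liver is the hottest large soft-tissue organ; per-coronal-plane
#' thresholding (relative to the soft-tissue median) and 2D labeling keep,
#' in each plane, the largest region whose centroid lies in the patient-right
#' half of the AC span and the superior half of the TH-NS span. The largest
#' 3D union over planes is the liver.
#'
#' @param volume an [suv_volume].
#' @param body the body `binary_mask`.
#' @param planes list with `ns_z`, `th_z`, `ac_left_x`, `ac_right_x`.
#' @param config a [pet_config]; `config$liver$side` names the half of the
#'   x axis holding the liver (`"high_x"` under the internal left-to-right
#'   axis convention).
#' @return A `binary_mask`; errors with class `liver_not_found` when no
#'   candidate exists.
#' @export
segment_liver <- function(volume, body, planes, config = pet_config()) {
  if (!any(body$data)) stop("empty body mask", call. = FALSE)
  p <- config$liver
  med <- stats::median(volume$data[body$data])
  thr <- p$threshold_rel * med
  span <- planes$ns_z - planes$th_z
  z_win <- c(planes$th_z + 0.5 * span, planes$ns_z)
  xmid <- (planes$ac_left_x + planes$ac_right_x) / 2
  x_win <- if (identical(p$side, "high_x")) c(xmid, planes$ac_right_x)
           else c(planes$ac_left_x, xmid)
  d <- dim(volume$data)
  cand <- array(FALSE, d)
  for (y in seq_len(d[2])) {
    k <- .coronal_candidates(volume$data[, y, ], thr, p$min_size_2d,
                             x_win, z_win, largest_only = TRUE)
    if (!is.null(k)) cand[, y, ] <- k
  }
  cand <- cand & body$data
  if (!any(cand)) {
    cnd <- simpleError("no liver candidate region above threshold")
    class(cnd) <- c("liver_not_found", class(cnd))
    stop(cnd)
  }
  L <- label_components(cand)
  sizes <- tabulate(L[L > 0L])
  binary_mask(L == which.max(sizes), spacing = volume$spacing)
}
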