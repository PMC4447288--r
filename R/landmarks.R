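#' Torso bounding planes
#'
#' The eight planes that confine the torso: the neck-shoulder (NS) and
#' thigh-hips (TH) axial planes, the bladder (BL) and liver (LV) axial organ
#' planes, the left/right arms-chest (AC) sagittal planes and the
#' anterior/posterior (A, P) coronal planes. Axial planes are 1-based z
#' slice indices and must satisfy TH < BL < LV < NS.
#'
#' @param ns_z,th_z,bl_z,lv_z axial slice indices.
#' @param ac_left_x,ac_right_x sagittal slice indices, left < right.
#' @param a_y,p_y coronal slice indices, anterior < posterior.
#' @param grid_shape optional grid dimensions for bounds checking.
#' @return Object of class `torso_planes`.
#' @export
torso_planes <- function(ns_z, th_z, bl_z, lv_z, ac_left_x, ac_right_x,
                         a_y, p_y, grid_shape = NULL) {
  v <- c(ns_z = ns_z, th_z = th_z, bl_z = bl_z, lv_z = lv_z,
         ac_left_x = ac_left_x, ac_right_x = ac_right_x,
         a_y = a_y, p_y = p_y)
  if (anyNA(v) || any(!is.finite(v)))
    stop("all plane indices must be finite", call. = FALSE)
  v <- round(v)
  if (!(th_z < bl_z && bl_z < lv_z && lv_z < ns_z))
    stop("axial planes must be strictly ordered TH < BL < LV < NS, got TH=",
         th_z, " BL=", bl_z, " LV=", lv_z, " NS=", ns_z, call. = FALSE)
  if (ac_left_x >= ac_right_x)
    stop("left AC plane must lie left of right AC plane", call. = FALSE)
  if (a_y >= p_y)
    stop("A plane must lie anterior to P plane", call. = FALSE)
  if (!is.null(grid_shape)) {
    if (any(v < 1) || ns_z > grid_shape[3] || th_z < 1 ||
        ac_right_x > grid_shape[1] || p_y > grid_shape[2])
      stop("plane indices must lie inside the grid", call. = FALSE)
  }
  structure(as.list(v), class = "torso_planes")
}

#' @export
print.torso_planes <- function(x, ...) {
  cat(sprintf(
    "torso planes: NS z=%d, LV z=%d, BL z=%d, TH z=%d; AC x=%d/%d; A/P y=%d/%d\n",
    x$ns_z, x$lv_z, x$bl_z, x$th_z, x$ac_left_x, x$ac_right_x, x$a_y, x$p_y))
  invisible(x)
}

#' Detect the neck-shoulder (NS) plane
#'
#' The axial plane of minimum body cross-sectional area, searched within the
#' superior portion of the body's z extent (so the global minimum cannot be
#' captured by the thigh region); ties break toward the superior slice.
#'
#' @param body a `binary_mask` of the body region.
#' @param band_frac fraction of the body's z extent, measured from the top,
#'   that forms the neck search band.
#' @param min_area_frac slices whose area falls below this fraction of the
#'   maximum axial body area do not count as body slices (they are residual
#'   noise attached to the mask, not anatomy).
#' @return Axial slice index.
#' @export
detect_ns_plane <- function(body, band_frac = 0.35, min_area_frac = 0.05) {
  area <- apply(body$data, 3L, sum)
  nz <- which(area > 0)
  if (length(nz) == 0L) stop("empty body mask", call. = FALSE)
  nz <- nz[area[nz] >= min_area_frac * max(area)]
  zmin <- min(nz); zmax <- max(nz)
  lo <- ceiling(zmax - band_frac * (zmax - zmin))
  band <- nz[nz >= lo]
  if (length(band) == 0L)
    stop("no nonzero-area slice in the neck search band", call. = FALSE)
  cand <- band[area[band] == min(area[band])]
  max(cand)
}

#' Detect the arms-chest (AC) planes from the sagittal body profile
#'
#' The profile of total body voxels per sagittal plane shows a central
#' maximum (the torso) flanked by two dips (the axillae, where only the
#' shoulder girdle spans the gap between arm and chest) and two lateral arm
#' bumps. Scanning outward from the central maximum, the first local minimum
#' deep enough relative to the peak and followed by a rise is the axilla.
#'
#' @param body a `binary_mask`.
#' @param smooth width of the moving-average window applied to the profile.
#' @param min_ratio a dip only counts as an axilla if the smoothed profile
#'   there falls below `min_ratio` times the central peak.
#' @return Integer vector `c(left, right)` of sagittal slice indices.
#' @export
detect_ac_planes <- function(body, smooth = 3, min_ratio = 0.6) {
  prof <- apply(body$data, 1L, sum)
  if (all(prof == 0)) stop("empty body mask", call. = FALSE)
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    sm <- stats::filter(prof, k, sides = 2)
    sm[is.na(sm)] <- prof[is.na(sm)]
    sm <- as.numeric(sm)
  } else sm <- prof
  pk <- which.max(sm)
  thr <- min_ratio * sm[pk]
  find_dip <- function(idx) {
    for (x in idx) {
      if (sm[x] == 0) break
      lower <- sm[x] <= sm[x - 1L] && sm[x] <= sm[x + 1L]
      outward <- if (x < pk) seq_len(x - 1L) else seq(x + 1L, length(sm))
      if (lower && sm[x] < thr && max(sm[outward]) > sm[x])
        return(x)
    }
    NA_integer_
  }
  n <- length(sm)
  left <- if (pk > 2L) find_dip(seq(pk - 1L, 2L)) else NA_integer_
  right <- if (pk < n - 1L) find_dip(seq(pk + 1L, n - 1L)) else NA_integer_
  if (is.na(left) || is.na(right))
    stop("no axilla found: sagittal body profile is unimodal ",
         "(armless subject or arms fused to the trunk)", call. = FALSE)
  c(left = left, right = right)
}

#' Detect the thigh-hips (TH) plane
#'
#' Scanning axial slices in the tail-to-head direction, slices whose body
#' cross-section consists of exactly two large connected components are
#' thigh slices; the TH plane is the first subsequent slice where those
#' components have united into one. Components smaller than `min_size`
#' voxels are ignored as noise specks.
#'
#' @param body a `binary_mask`.
#' @param min_size minimum 2D component size, in voxels, to count as a limb.
#' @return Axial slice index.
#' @export
detect_th_plane <- function(body, min_size = 50) {
  d <- dim(body$data)
  seen_two <- FALSE
  for (z in seq_len(d[3])) {
    sl <- body$data[, , z]
    if (!any(sl)) next
    L <- label_components(sl)
    sizes <- tabulate(L[L > 0L])
    nlarge <- sum(sizes >= min_size)
    if (nlarge == 2L) seen_two <- TRUE
    if (seen_two && nlarge == 1L) return(z)
  }
  stop("thighs never unite: no axial slice shows two large components ",
       "followed by one (legs fused or cropped)", call. = FALSE)
}

#' Detect the anterior and posterior (A, P) planes
#'
#' First and last coronal planes with nonzero body area, computed over
#' slices at or below the NS plane so that a protruding head cannot shift
#' the boundaries.
#'
#' @param body a `binary_mask`.
#' @param ns_z the detected NS plane.
#' @return Integer vector `c(a, p)` of coronal slice indices.
#' @export
detect_ap_planes <- function(body, ns_z) {
  sub <- body$data[, , seq_len(ns_z), drop = FALSE]
  yprof <- apply(sub, 2L, sum)
  nz <- which(yprof > 0)
  if (length(nz) == 0L)
    stop("empty coronal profile below the NS plane", call. = FALSE)
  c(a = min(nz), p = max(nz))
}

#' Compute the bladder (BL) plane
#'
#' For every coronal plane intersecting the bladder mask, the centroid of
#' each 2D bladder label is computed; the BL plane is the mean of the
#' centroids' z coordinates, rounded half-up.
#'
#' @param bladder a `binary_mask` of the bladder.
#' @return Axial slice index.
#' @export
compute_bl_plane <- function(bladder) {
  if (!any(bladder$data)) stop("empty bladder mask", call. = FALSE)
  d <- dim(bladder$data)
  cz <- numeric(0)
  for (y in seq_len(d[2])) {
    sl <- bladder$data[, y, ]
    if (!any(sl)) next
    L <- label_components(sl)
    for (lab in seq_len(max(L))) {
      w <- which(L == lab, arr.ind = TRUE)
      if (nrow(w) > 0L) cz <- c(cz, mean(w[, 2]))
    }
  }
  as.integer(floor(mean(cz) + 0.5))
}

#' Compute the liver (LV) plane
#'
#' The apex of the liver toward the head marks the liver/lung boundary: the
#' LV plane is the maximum z index over liver voxels.
#'
#' @param liver a `binary_mask` of the liver.
#' @return Axial slice index.
#' @export
compute_lv_plane <- function(liver) {
  if (!any(liver$data)) stop("empty liver mask", call. = FALSE)
  max(which(liver$data, arr.ind = TRUE)[, 3])
}

#' Assemble the 16-corner landmark set from the torso planes
#'
#' All combinations of the two AC planes, the two A/P planes and the four
#' axial levels give 16 corner points: S1-S4 on the NS plane, LV1-LV4 on the
#' liver plane, BL1-BL4 on the bladder plane and T1-T4 on the TH plane.
#' Within each level, corner 1 is (left, anterior), 2 (right, anterior),
#' 3 (right, posterior), 4 (left, posterior), so that the anterior face is
#' {S1, S2, T2, T1} and the left face {S1, T1, T4, S4}.
#'
#' @param planes a [torso_planes].
#' @return A 16 x 3 matrix of voxel coordinates with row names
#'   `S1..S4, LV1..LV4, BL1..BL4, T1..T4`, of class `landmark_set`.
#' @export
assemble_landmarks <- function(planes) {
  stopifnot(inherits(planes, "torso_planes"))
  levels <- c(S = planes$ns_z, LV = planes$lv_z, BL = planes$bl_z,
              T = planes$th_z)
  corners <- rbind(c(planes$ac_left_x,  planes$a_y),
                   c(planes$ac_right_x, planes$a_y),
                   c(planes$ac_right_x, planes$p_y),
                   c(planes$ac_left_x,  planes$p_y))
  pts <- matrix(0, 16L, 3L, dimnames = list(NULL, c("x", "y", "z")))
  nm <- character(16L)
  i <- 0L
  for (lev in names(levels)) for (k in 1:4) {
    i <- i + 1L
    pts[i, ] <- c(corners[k, ], levels[[lev]])
    nm[i] <- paste0(lev, k)
  }
  rownames(pts) <- nm
  structure(pts, class = c("landmark_set", "matrix", "array"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark set (16 cuboid corners):\n")
  print(unclass(x))
  invisible(x)
}

# planes implied by a landmark set (inverse of assemble_landmarks)
planes_from_landmarks <- function(lm) {
  torso_planes(ns_z = lm["S1", "z"], th_z = lm["T1", "z"],
               bl_z = lm["BL1", "z"], lv_z = lm["LV1", "z"],
               ac_left_x = lm["S1", "x"], ac_right_x = lm["S2", "x"],
               a_y = lm["S1", "y"], p_y = lm["S3", "y"])
}

#' Detect all eight torso planes of a volume
#'
#' Runs the full rule-based plane detection: body extraction, NS/AC/TH/A-P
#' physique planes, then bladder and liver segmentation for the BL and LV
#' organ planes. If the bladder cannot be found, BL falls back to the slice
#' at a configurable fraction of the TH-NS span (flagged in the report).
#'
#' @param volume an [suv_volume].
#' @param config a [pet_config] list of tunables.
#' @param body optional precomputed body `binary_mask`.
#' @return List with elements `planes` (a [torso_planes]), `landmarks`
#'   (a `landmark_set`), `body`, `bladder`, `liver` masks, and `report`
#'   (detected values and fallback flags).
#' @export
detect_torso_planes <- function(volume, config = pet_config(), body = NULL) {
  if (is.null(body)) body <- extract_body_mask(volume, config$body_threshold)
  ns <- detect_ns_plane(body, config$ns_band_frac, config$ns_min_area_frac)
  ac <- detect_ac_planes(body, config$ac_smooth, config$ac_min_ratio)
  th <- detect_th_plane(body, config$th_min_size)
  ap <- detect_ap_planes(body, ns)
  phys <- list(ns_z = ns, th_z = th, ac_left_x = ac[["left"]],
               ac_right_x = ac[["right"]], a_y = ap[["a"]], p_y = ap[["p"]])
  bladder <- NULL
  bl_fallback <- FALSE
  bl <- tryCatch({
    bladder <- segment_bladder(volume, body, phys, config)
    compute_bl_plane(bladder)
  }, error = function(e) {
    bl_fallback <<- TRUE
    as.integer(round(th + config$bl_fallback_frac * (ns - th)))
  })
  liver <- segment_liver(volume, body, phys, config)
  lv <- compute_lv_plane(liver)
  planes <- torso_planes(ns_z = ns, th_z = th, bl_z = bl, lv_z = lv,
                         ac_left_x = phys$ac_left_x,
                         ac_right_x = phys$ac_right_x,
                         a_y = phys$a_y, p_y = phys$p_y,
                         grid_shape = dim(volume$data))
  list(planes = planes, landmarks = assemble_landmarks(planes),
       body = body, bladder = bladder, liver = liver,
       report = list(planes = unclass(planes), bl_fallback = bl_fallback))
}
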