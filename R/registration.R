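# Deformation of a subject volume onto the standard body: piecewise affine
# mapping of the 16-corner landmark cuboid, then thin-plate-spline surface
# registration, with nearest-neighbor pull-back resampling throughout.

# piecewise-linear z map through the four axial plane knots (TH, BL, LV,
# NS), linearly extended beyond the end knots; x and y are single linear
# maps through the AC and A/P planes, shared by all slabs (hence the three
# z slabs agree on their boundary planes by construction)
.axis_maps <- function(from, to) {
  lin <- function(f1, f2, t1, t2) {
    a <- (t2 - t1) / (f2 - f1)
    function(v) t1 + (v - f1) * a
  }
  zk_f <- c(from$th_z, from$bl_z, from$lv_z, from$ns_z)
  zk_t <- c(to$th_z, to$bl_z, to$lv_z, to$ns_z)
  zmap <- function(z) {
    seg <- pmin(pmax(findInterval(z, zk_f), 1L), 3L)
    zk_t[seg] + (z - zk_f[seg]) *
      (zk_t[seg + 1L] - zk_t[seg]) / (zk_f[seg + 1L] - zk_f[seg])
  }
  list(x = lin(from$ac_left_x, from$ac_right_x, to$ac_left_x, to$ac_right_x),
       y = lin(from$a_y, from$p_y, to$a_y, to$p_y),
       z = zmap)
}

#' Map points through the piecewise affine cuboid transform
#'
#' Forward mapping from the source landmark cuboid onto the destination
#' cuboid: x and y are linear maps through the AC and A/P planes; z is
#' piecewise linear through the TH, BL, LV and NS planes (three slabs,
#' continuous at the shared BL and LV boundary planes and linearly extended
#' beyond TH and NS). All 16 landmark corners map exactly onto their
#' destination counterparts.
#'
#' @param points m x 3 matrix of (x, y, z) voxel coordinates.
#' @param src,dst `landmark_set` objects (source and destination).
#' @return m x 3 matrix of mapped coordinates.
#' @export
map_cuboid_points <- function(points, src, dst) {
  maps <- .axis_maps(planes_from_landmarks(src), planes_from_landmarks(dst))
  cbind(maps$x(points[, 1]), maps$y(points[, 2]), maps$z(points[, 3]))
}

#' Deform a volume by the piecewise affine cuboid transform
#'
#' Pulls the source volume onto the destination grid: for each output voxel
#' the inverse cuboid map gives the source position, and the nearest source
#' voxel is copied (no voxel gaps can arise). With `mode = "global"` a
#' single 12-dof affine transform, fitted by least squares over the 16
#' landmark pairs, replaces the piecewise map.
#'
#' @param volume an [suv_volume].
#' @param src the subject's `landmark_set`.
#' @param dst the standard body's `landmark_set`.
#' @param out_shape,out_spacing geometry of the output (standard) grid.
#' @param mode `"piecewise"` (exact at all 16 corners) or `"global"`.
#' @return An [suv_volume] on the output grid; out-of-field voxels are 0.
#' @export
map_cuboid <- function(volume, src, dst,
                       out_shape = dim(volume$data),
                       out_spacing = volume$spacing,
                       mode = c("piecewise", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "suv_volume"))
  pl_src <- planes_from_landmarks(src)   # validates ordering
  pl_dst <- planes_from_landmarks(dst)
  d <- dim(volume$data)
  if (mode == "piecewise") {
    inv <- .axis_maps(pl_dst, pl_src)    # dst -> src pull-back
    mx <- as.integer(round(inv$x(seq_len(out_shape[1]))))
    my <- as.integer(round(inv$y(seq_len(out_shape[2]))))
    mz <- as.integer(round(inv$z(seq_len(out_shape[3]))))
    # out-of-range source indices hit a zero-padding sentinel
    pad <- function(idx, n) { idx[idx < 1L | idx > n] <- n + 1L; idx }
    padded <- array(0, d + c(1L, 1L, 1L))
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- volume$data
    out <- padded[pad(mx, d[1]), pad(my, d[2]), pad(mz, d[3])]
  } else {
    # least-squares affine dst -> src over the 16 corners
    B <- cbind(1, unclass(dst))
    co <- qr.solve(B, unclass(src))      # 4 x 3
    gx <- seq_len(out_shape[1]); gy <- seq_len(out_shape[2])
    gz <- seq_len(out_shape[3])
    pts <- cbind(1,
                 rep(gx, times = out_shape[2] * out_shape[3]),
                 rep(rep(gy, each = out_shape[1]), times = out_shape[3]),
                 rep(gz, each = out_shape[1] * out_shape[2]))
    sidx <- round(pts %*% co)
    ok <- sidx[, 1] >= 1 & sidx[, 1] <= d[1] &
          sidx[, 2] >= 1 & sidx[, 2] <= d[2] &
          sidx[, 3] >= 1 & sidx[, 3] <= d[3]
    out <- numeric(prod(out_shape))
    lin <- (sidx[ok, 3] - 1) * d[1] * d[2] + (sidx[ok, 2] - 1) * d[1] +
      sidx[ok, 1]
    out[ok] <- volume$data[lin]
    out <- array(out, out_shape)
  }
  suv_volume(out, spacing = out_spacing, sex = volume$sex, id = volume$id)
}

#' Place surface control points on the body contour
#'
#' At each requested axial level, rays are cast from the slice's body
#' centroid at `angular_step`-degree intervals; each control point is the
#' last body voxel along its ray. Points are ordered level-major,
#' angle-minor, and tagged with their (level, angle) so corresponding
#' points on two bodies can be matched.
#'
#' @param body a `binary_mask`.
#' @param levels axial slice indices carrying control points.
#' @param angular_step angular spacing in degrees; must divide 360.
#' @return Object of class `surface_points`: a list with `points`
#'   (n x 3 matrix), `level`, `angle` (degrees), `angular_step`, `levels`.
#' @export
place_surface_points <- function(body, levels, angular_step = 15) {
  stopifnot(360 %% angular_step == 0)
  levels <- as.integer(round(levels))
  d <- dim(body$data)
  nang <- as.integer(360 / angular_step)
  angles <- (seq_len(nang) - 1L) * angular_step
  rad <- angles * pi / 180
  ts <- seq(0, sqrt(d[1]^2 + d[2]^2), by = 0.25)
  pts <- matrix(NA_real_, length(levels) * nang, 3L)
  lev_tag <- integer(0); ang_tag <- numeric(0)
  i <- 0L
  for (z in levels) {
    sl <- body$data[, , z]
    if (!any(sl))
      stop("body slice at level z=", z, " is empty; cannot place surface ",
           "points there", call. = FALSE)
    w <- which(sl, arr.ind = TRUE)
    cx <- mean(w[, 1]); cy <- mean(w[, 2])
    for (k in seq_len(nang)) {
      px <- pmin(pmax(as.integer(round(cx + ts * cos(rad[k]))), 1L), d[1])
      py <- pmin(pmax(as.integer(round(cy + ts * sin(rad[k]))), 1L), d[2])
      on <- sl[cbind(px, py)]
      last <- max(which(on))
      i <- i + 1L
      pts[i, ] <- c(px[last], py[last], z)
      lev_tag <- c(lev_tag, z); ang_tag <- c(ang_tag, angles[k])
    }
  }
  structure(list(points = pts, level = lev_tag, angle = ang_tag,
                 angular_step = angular_step, levels = as.integer(levels)),
            class = "surface_points")
}

#' @export
print.surface_points <- function(x, ...) {
  cat(sprintf("surface points: %d points (%d levels x %d angles, %g deg)\n",
              nrow(x$points), length(x$levels), 360 / x$angular_step,
              x$angular_step))
  invisible(x)
}

.as_points <- function(x) {
  if (inherits(x, "surface_points")) x$points
  else if (inherits(x, "landmark_set")) unclass(x)
  else as.matrix(x)
}

#' Fit a 3D thin-plate spline between corresponding point sets
#'
#' Solves the standard TPS system with the 3D biharmonic kernel
#' U(r) = -r (the conditionally positive definite sign convention):
#' an affine part plus radial kernel corrections anchored at the source
#' points. At `lambda = 0` the transform interpolates exactly (every source
#' point maps onto its counterpart); `lambda > 0` trades anchor fidelity
#' for smoothness. The kernel weights satisfy the TPS side conditions
#' (zero sum, orthogonal to the anchor coordinates).
#'
#' @param src source points: a `surface_points`, `landmark_set` or n x 3
#'   matrix. When both `src` and `dst` are `surface_points`, their (level,
#'   angle) tags must correspond one-to-one.
#' @param dst destination points, same form and count as `src`.
#' @param lambda smoothing scalar, >= 0.
#' @return Object of class `tps_transform` with elements `anchors`,
#'   `weights` (n x 3), `affine` (4 x 3), `lambda`.
#' @export
fit_tps <- function(src, dst, lambda = 0) {
  if (inherits(src, "surface_points") && inherits(dst, "surface_points")) {
    if (!identical(src$level, dst$level) ||
        !identical(src$angle, dst$angle))
      stop("source and destination surface points must share (level, ",
           "angle) tags", call. = FALSE)
  }
  A <- .as_points(src); V <- .as_points(dst)
  if (nrow(A) != nrow(V))
    stop("point counts differ: ", nrow(A), " vs ", nrow(V), call. = FALSE)
  # coincident source anchors (e.g. adjacent rays hitting the same surface
  # voxel on a narrow slice) would make the system exactly singular; merge
  # them, averaging their targets
  key <- paste(A[, 1], A[, 2], A[, 3])
  if (anyDuplicated(key)) {
    grp <- match(key, unique(key))
    A <- A[!duplicated(key), , drop = FALSE]
    V <- rowsum(V, grp) / as.vector(table(grp))
  }
  n <- nrow(A)
  if (n < 5L) stop("need at least 5 anchor points in 3D", call. = FALSE)
  # U(r) = -r: the conditionally positive definite 3D biharmonic kernel,
  # so K + lambda*I stays well-posed for all smoothing levels
  K <- -as.matrix(stats::dist(A))
  P <- cbind(1, A)
  M <- rbind(cbind(K + diag(lambda, n), P),
             cbind(t(P), matrix(0, 4L, 4L)))
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-14)
    stop("degenerate anchor configuration: TPS system is singular ",
         sprintf("(reciprocal condition number %.2e); ", rc),
         "anchors may be coplanar or duplicated", call. = FALSE)
  sol <- solve(M, rbind(V, matrix(0, 4L, 3L)))
  structure(list(anchors = A, targets = V,
                 weights = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:4, , drop = FALSE],
                 lambda = lambda),
            class = "tps_transform")
}

#' Evaluate a thin-plate-spline transform at points
#'
#' @param object a `tps_transform`.
#' @param newdata m x 3 matrix of coordinates.
#' @param ... unused.
#' @return m x 3 matrix of mapped coordinates.
#' @export
predict.tps_transform <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  stopifnot(ncol(X) == 3L)
  storage.mode(X) <- "double"
  tps_eval_cpp(X, object$anchors, object$weights, object$affine)
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("thin-plate-spline transform: %d anchors, lambda = %g\n",
              nrow(x$anchors), x$lambda))
  cat(sprintf("  max |kernel weight| = %.3g, weight column sums = %s\n",
              max(abs(x$weights)),
              paste(sprintf("%.2e", colSums(x$weights)), collapse = ", ")))
  invisible(x)
}

#' Resample a volume through a transform with nearest-neighbor pull-back
#'
#' For each output voxel the transform gives the source position (the
#' transform maps output space into source space) and the nearest source
#' voxel is copied; positions outside the source field of view become 0.
#' Nearest-neighbor never invents intensities: every output value occurs in
#' the input (or is 0).
#'
#' @param volume an [suv_volume] (source).
#' @param transform a `tps_transform` mapping output coordinates to source
#'   coordinates, or `NULL` for the identity.
#' @param out_shape,out_spacing output grid geometry.
#' @return An [suv_volume] on the output grid.
#' @export
resample_nn <- function(volume, transform,
                        out_shape = dim(volume$data),
                        out_spacing = volume$spacing) {
  stopifnot(inherits(volume, "suv_volume"))
  d <- dim(volume$data)
  if (is.null(transform)) {
    out <- array(0, out_shape)
    cp <- pmin(d, out_shape)
    out[seq_len(cp[1]), seq_len(cp[2]), seq_len(cp[3])] <-
      volume$data[seq_len(cp[1]), seq_len(cp[2]), seq_len(cp[3])]
  } else {
    gx <- seq_len(out_shape[1]); gy <- seq_len(out_shape[2])
    gz <- seq_len(out_shape[3])
    pts <- cbind(rep(gx, times = out_shape[2] * out_shape[3]),
                 rep(rep(gy, each = out_shape[1]), times = out_shape[3]),
                 rep(gz, each = out_shape[1] * out_shape[2]))
    sidx <- round(predict(transform, pts))
    ok <- sidx[, 1] >= 1 & sidx[, 1] <= d[1] &
          sidx[, 2] >= 1 & sidx[, 2] <= d[2] &
          sidx[, 3] >= 1 & sidx[, 3] <= d[3]
    out <- numeric(prod(out_shape))
    lin <- (sidx[ok, 3] - 1) * d[1] * d[2] + (sidx[ok, 2] - 1) * d[1] +
      sidx[ok, 1]
    out[ok] <- volume$data[lin]
    out <- array(out, out_shape)
  }
  suv_volume(out, spacing = out_spacing, sex = volume$sex, id = volume$id)
}

#' Define a standard body from a reference volume
#'
#' One standard body per sex anchors the standard space: its eight planes
#' and 16 landmarks are detected from the reference volume, and surface
#' control points are placed at `level_spacing`-slice intervals across the
#' TH-NS span at `angular_step`-degree intervals.
#'
#' @param volume the reference [suv_volume] (e.g. a representative normal
#'   case or a noiseless phantom).
#' @param config a [pet_config].
#' @return Object of class `standard_body` with `landmarks`, `planes`,
#'   `surface_points`, `body_mask`, `grid_shape`, `spacing`, `sex`.
#' @export
standard_body <- function(volume, config = pet_config()) {
  det <- detect_torso_planes(volume, config)
  levels <- seq(det$planes$th_z, det$planes$ns_z,
                by = config$surface$level_spacing)
  sp <- place_surface_points(det$body, levels,
                             config$surface$angular_step)
  structure(list(landmarks = det$landmarks, planes = det$planes,
                 surface_points = sp, body_mask = det$body,
                 grid_shape = dim(volume$data), spacing = volume$spacing,
                 sex = volume$sex, id = volume$id),
            class = "standard_body")
}

#' @export
print.standard_body <- function(x, ...) {
  cat(sprintf("standard body (%s): grid %s, %d surface control points\n",
              x$sex, paste(x$grid_shape, collapse = "x"),
              nrow(x$surface_points$points)))
  print(x$planes)
  invisible(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Standardize a volume onto the standard body
#'
#' Runs the full three-step registration: physique/organ plane detection
#' and piecewise affine cuboid mapping, then thin-plate-spline surface
#' registration against the standard's surface control points, with
#' nearest-neighbor pull-back resampling onto the standard grid.
#'
#' @param volume an [suv_volume]; its sex tag must match the standard's.
#' @param standard a [standard_body].
#' @param config a [pet_config].
#' @return List with `volume` (the standardized [suv_volume]) and `report`
#'   (detected planes, bladder fallback flag, surface point count, maximum
#'   TPS anchor residual in voxels).
#' @export
standardize <- function(volume, standard, config = pet_config()) {
  stopifnot(inherits(volume, "suv_volume"), inherits(standard, "standard_body"))
  if (volume$sex != standard$sex)
    stop("sex mismatch: volume is '", volume$sex, "' but the standard body ",
         "is '", standard$sex, "'", call. = FALSE)
  det <- .stage("plane-detection", detect_torso_planes(volume, config))
  cub <- .stage("cuboid-mapping",
    map_cuboid(volume, det$landmarks, standard$landmarks,
               out_shape = standard$grid_shape,
               out_spacing = standard$spacing, mode = config$slab_mode))
  body2 <- .stage("surface-extraction",
    extract_body_mask(cub, config$body_threshold))
  sp <- .stage("surface-extraction",
    place_surface_points(body2, standard$surface_points$levels,
                         standard$surface_points$angular_step))
  tps <- .stage("surface-registration",
    fit_tps(standard$surface_points, sp, lambda = config$tps_lambda))
  out <- .stage("resampling",
    resample_nn(cub, tps, out_shape = standard$grid_shape,
                out_spacing = standard$spacing))
  resid <- predict(tps, tps$anchors) - tps$targets
  report <- list(planes = det$report$planes,
                 bl_fallback = det$report$bl_fallback,
                 n_surface_points = nrow(sp$points),
                 tps_max_anchor_residual = max(abs(resid)),
                 slab_mode = config$slab_mode)
  list(volume = out, report = report)
}
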