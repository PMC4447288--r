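#' Voxel Z-score
#'
#' The pixel-by-pixel abnormality index: `Z = (P - M) / SD`, where P is the
#' deformed patient SUV and M, SD the normal model's mean and standard
#' deviation at the same standard-space voxel. A raw SUV that looks alarming
#' can be normal (a bladder SUV of 65.4 against mean 19.6 and SD 24.9 gives
#' Z = 1.84) while a modest SUV can be highly abnormal (2.1 against mean
#' 0.61, SD 0.26 gives Z = 5.73): the score measures deviation from the
#' local normal range, not raw uptake.
#'
#' @param p patient SUV (vectorized).
#' @param m model mean SUV.
#' @param sd model SD.
#' @param sd_floor SDs below this floor mark the voxel invalid (`NA`),
#'   rather than producing explosive scores in near-constant regions.
#' @return Numeric Z values; `NA` where `sd < sd_floor`.
#' @examples
#' zscore_voxel(2.1, 0.61, 0.26)   # 5.73
#' zscore_voxel(65.4, 19.6, 24.9)  # 1.84
#' @export
zscore_voxel <- function(p, m, sd, sd_floor = 0.05) {
  z <- (p - m) / sd
  z[sd < sd_floor] <- NA_real_
  z
}

#' Voxel-wise Z-score map of a standardized volume
#'
#' @param volume a standardized [suv_volume] on the model grid.
#' @param model a [normal_model].
#' @param sd_floor SD validity floor in SUV units.
#' @return Object of class `zscore_map` with `z` (3D grid, `NA` where
#'   invalid), `valid` (logical grid: model-valid voxels with SD at or
#'   above the floor), `model_ref`, `spacing`.
#' @export
zscore_map <- function(volume, model, sd_floor = 0.05) {
  stopifnot(inherits(volume, "suv_volume"), inherits(model, "normal_model"))
  if (!identical(dim(volume$data), model$grid_shape))
    stop("volume grid ", paste(dim(volume$data), collapse = "x"),
         " does not match the model grid ",
         paste(model$grid_shape, collapse = "x"), call. = FALSE)
  valid <- model$valid & model$sd >= sd_floor
  z <- (volume$data - model$mean) / model$sd
  z[!valid] <- NA_real_
  structure(list(z = z, valid = valid,
                 model_ref = sprintf("%s-n%d", model$sex, model$n),
                 spacing = volume$spacing),
            class = "zscore_map")
}

#' @export
print.zscore_map <- function(x, ...) {
  cat(sprintf("Z-score map: %s voxels, %d valid\n",
              paste(dim(x$z), collapse = " x "), sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  Z range on valid voxels: [%.2f, %.2f]\n",
                min(x$z[x$valid]), max(x$z[x$valid])))
  invisible(x)
}

#' Score a segmented spot
#'
#' Per-region readout in the conventional form: the region's SUVmax, the Z
#' at the SUVmax voxel (the headline single-voxel readout; ties in SUV
#' resolve to the highest Z among tied voxels), and the maximum and mean Z
#' over the region's model-valid voxels.
#'
#' @param zmap a `zscore_map`.
#' @param volume the standardized [suv_volume] the map was computed from.
#' @param spot a `binary_mask` (or logical array) on the standard grid.
#' @param spot_id identifier carried into the result.
#' @return Object of class `spot_score`: list with `spot_id`,
#'   `voxel_count`, `suv_max`, `z_at_suvmax`, `z_max`, `z_mean`.
#' @export
score_spot <- function(zmap, volume, spot, spot_id = "spot") {
  sel <- if (inherits(spot, "binary_mask")) spot$data else spot
  if (!identical(dim(sel), dim(zmap$z)))
    stop("spot grid does not match the Z-map grid", call. = FALSE)
  idx <- which(sel)
  if (length(idx) == 0L) stop("empty spot mask", call. = FALSE)
  vidx <- idx[zmap$valid[idx]]
  if (length(vidx) == 0L)
    stop("spot '", spot_id, "' lies entirely in model-invalid voxels",
         call. = FALSE)
  suv <- volume$data[idx]
  suv_max <- max(suv)
  at_max <- idx[suv == suv_max]
  zm <- zmap$z[at_max]
  z_at_suvmax <- if (all(is.na(zm))) NA_real_ else max(zm, na.rm = TRUE)
  zv <- zmap$z[vidx]
  structure(list(spot_id = spot_id, voxel_count = length(idx),
                 suv_max = suv_max, z_at_suvmax = z_at_suvmax,
                 z_max = max(zv), z_mean = mean(zv)),
            class = "spot_score")
}

#' @export
print.spot_score <- function(x, ...) {
  cat(sprintf(
    "spot '%s': %d voxels, SUVmax %.2f, Z@SUVmax %.2f, Zmax %.2f, Zmean %.2f\n",
    x$spot_id, x$voxel_count, x$suv_max, x$z_at_suvmax, x$z_max, x$z_mean))
  invisible(x)
}

#' Score several spots into a table
#'
#' @param zmap a `zscore_map`.
#' @param volume the standardized [suv_volume].
#' @param spots named list of spot masks.
#' @return data.frame with one row per spot (columns `spot_id`, `voxels`,
#'   `suv_max`, `z_at_suvmax`, `z_max`, `z_mean`), suitable for TSV export.
#' @export
score_spots <- function(zmap, volume, spots) {
  ids <- names(spots)
  if (is.null(ids)) ids <- sprintf("spot%02d", seq_along(spots))
  rows <- lapply(seq_along(spots), function(i) {
    s <- score_spot(zmap, volume, spots[[i]], spot_id = ids[i])
    data.frame(spot_id = s$spot_id, voxels = s$voxel_count,
               suv_max = s$suv_max, z_at_suvmax = s$z_at_suvmax,
               z_max = s$z_max, z_mean = s$z_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
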