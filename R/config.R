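#' Pipeline configuration
#'
#' Single source of tunables for the whole pipeline. Values may be
#' overridden individually via `...` (nested lists are merged key-wise) or
#' loaded from a YAML file with [read_config].
#'
#' Defaults: body threshold 0.5 SUV; NS search band = superior 35% of the
#' body z extent; TH limb components >= 50 voxels; AC profile smoothed over
#' 3 sagittal positions with axilla dips below 60% of the central peak;
#' bladder threshold max(5 SUV, 3 x soft-tissue median) searched in the
#' inferior 40% of the cuboid and medial 50% of the AC span; liver threshold
#' 1.3 x soft-tissue median in the patient-right/superior quadrant; BL
#' fallback at 30% of the TH-NS span; surface control points every 15
#' degrees on every 5th axial slice; TPS smoothing lambda 0 (exact
#' interpolation); SD floor 0.05 SUV for Z-scoring.
#'
#' @param ... named overrides, e.g. `body_threshold = 0.4` or
#'   `liver = list(side = "low_x")`.
#' @return A nested list of class `pet_config`.
#' @export
pet_config <- function(...) {
  cfg <- list(
    body_threshold = 0.5,
    ns_band_frac = 0.35,
    ns_min_area_frac = 0.05,
    th_min_size = 50,
    ac_smooth = 3,
    ac_min_ratio = 0.6,
    bl_fallback_frac = 0.30,
    bladder = list(threshold_abs = 5.0, threshold_rel = 3.0,
                   min_size_2d = 8, z_frac = 0.40, x_frac = 0.50),
    liver = list(threshold_rel = 1.3, min_size_2d = 20, side = "high_x"),
    surface = list(angular_step = 15, level_spacing = 5),
    tps_lambda = 0,
    slab_mode = "piecewise",
    sd_floor = 0.05
  )
  ov <- list(...)
  cfg <- .merge_config(cfg, ov)
  if (360 %% cfg$surface$angular_step != 0)
    stop("`angular_step` must divide 360", call. = FALSE)
  if (!cfg$slab_mode %in% c("piecewise", "global"))
    stop("`slab_mode` must be 'piecewise' or 'global'", call. = FALSE)
  structure(cfg, class = c("pet_config", "list"))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override [pet_config] defaults; nested keys
#' merge.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A `pet_config`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(pet_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ov <- yaml::read_yaml(path)
  do.call(pet_config, as.list(ov))
}
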