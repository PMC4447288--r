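#' Fit a voxel-wise normal model from standardized volumes
#'
#' Accumulates the per-voxel arithmetic mean and sample standard deviation
#' (n - 1 denominator) of SUV over a sequence of standardized normal scans,
#' in a single numerically stable streaming pass (Welford's update, applied
#' volume by volume in input order). The result is the sex-specific
#' statistical model against which patient scans are Z-scored: `M(x,y,z)`
#' and `SD(x,y,z)` grids in standard space.
#'
#' Sex stratification is mandatory: all volumes must carry the model's sex
#' tag. Voxels outside the standard body mask (when a standard is supplied)
#' are flagged invalid rather than carrying meaningless statistics.
#'
#' @param volumes list of [suv_volume]s, all on the standard grid.
#' @param sex `"male"` or `"female"`.
#' @param standard optional [standard_body]; supplies the valid-voxel mask
#'   and standard-space metadata.
#' @return Object of class `normal_model` with elements `mean`, `sd`
#'   (3D grids), `n`, `sex`, `valid` (logical grid), `grid_shape`,
#'   `spacing`, `standard` (landmark metadata or `NULL`).
#' @seealso [predict.normal_model] for Z-score maps, [model_summary],
#'   [save_model].
#' @examples
#' v1 <- suv_volume(array(1, c(4, 4, 4)), sex = "male")
#' v2 <- suv_volume(array(3, c(4, 4, 4)), sex = "male")
#' m <- normal_model(list(v1, v2), sex = "male")
#' m$mean[1, 1, 1]  # 2
#' m$sd[1, 1, 1]    # sqrt(2)
#' @export
normal_model <- function(volumes, sex = c("male", "female"),
                         standard = NULL) {
  sex <- match.arg(sex)
  n <- length(volumes)
  if (n < 2L)
    stop("a normal model needs at least 2 volumes, got ", n, call. = FALSE)
  d <- dim(volumes[[1L]]$data)
  spacing <- volumes[[1L]]$spacing
  for (i in seq_len(n)) {
    v <- volumes[[i]]
    if (!inherits(v, "suv_volume"))
      stop("element ", i, " is not an suv_volume", call. = FALSE)
    if (!identical(dim(v$data), d))
      stop("grid mismatch: volume ", i,
           if (nzchar(v$id)) paste0(" ('", v$id, "')") else "",
           " has dims ", paste(dim(v$data), collapse = "x"),
           ", expected ", paste(d, collapse = "x"), call. = FALSE)
    if (v$sex != sex)
      stop("sex mismatch: volume ", i, " is '", v$sex,
           "' but the model is stratified as '", sex,
           "'; mixed-sex models are refused", call. = FALSE)
  }
  if (!is.null(standard) && !identical(standard$grid_shape, d))
    stop("standard grid does not match the volumes", call. = FALSE)
  M <- array(0, d); S <- array(0, d)
  for (k in seq_len(n)) {
    x <- volumes[[k]]$data
    delta <- x - M
    M <- M + delta / k
    S <- S + delta * (x - M)
  }
  sdg <- sqrt(pmax(S, 0) / (n - 1))
  valid <- if (is.null(standard)) array(TRUE, d) else standard$body_mask$data
  structure(list(mean = M, sd = sdg, n = n, sex = sex, valid = valid,
                 grid_shape = d, spacing = spacing, standard = standard),
            class = "normal_model")
}

#' @export
print.normal_model <- function(x, ...) {
  cat(sprintf("normal model (%s, n = %d cases)\n", x$sex, x$n))
  cat(sprintf("  grid  : %s voxels, spacing %s mm\n",
              paste(x$grid_shape, collapse = " x "),
              paste(signif(x$spacing, 3), collapse = " x ")))
  cat(sprintf("  valid : %d voxels (%.1f%%)\n", sum(x$valid),
              100 * mean(x$valid)))
  cat(sprintf("  mean SUV in valid region: %.3g (SD grid median %.3g)\n",
              mean(x$mean[x$valid]), stats::median(x$sd[x$valid])))
  invisible(x)
}

#' Summarize a normal model over a region
#'
#' @param object a [normal_model].
#' @param region optional `binary_mask` (or logical array) on the model
#'   grid; defaults to the model's valid region.
#' @param ... unused.
#' @return List with `n_voxels`, `mean` (mean of the voxel means), `sd`
#'   (pooled SD, the root mean square of voxel SDs) and `range` (max - min
#'   of the mean grid within the region).
#' @export
summary.normal_model <- function(object, region = NULL, ...) {
  model_summary(object, region)
}

#' @rdname summary.normal_model
#' @param model a [normal_model].
#' @export
model_summary <- function(model, region = NULL) {
  sel <- if (is.null(region)) model$valid
         else if (inherits(region, "binary_mask")) region$data
         else region
  if (!identical(dim(sel), model$grid_shape))
    stop("region grid does not match the model grid", call. = FALSE)
  if (!any(sel)) stop("empty region", call. = FALSE)
  mu <- model$mean[sel]
  structure(list(n_voxels = sum(sel), mean = mean(mu),
                 sd = sqrt(mean(model$sd[sel]^2)),
                 range = max(mu) - min(mu)),
            class = "normal_model_summary")
}

#' @export
print.normal_model_summary <- function(x, ...) {
  cat(sprintf(
    "region of %d voxels: mean SUV %.3f, pooled SD %.3f, range %.3f\n",
    x$n_voxels, x$mean, x$sd, x$range))
  invisible(x)
}

#' Z-score a standardized volume against a normal model
#'
#' @param object a [normal_model].
#' @param newdata a standardized [suv_volume] on the model grid.
#' @param sd_floor voxels with model SD below this are invalid.
#' @param ... unused.
#' @return A `zscore_map`; see [zscore_map].
#' @export
predict.normal_model <- function(object, newdata, sd_floor = 0.05, ...) {
  zscore_map(newdata, object, sd_floor = sd_floor)
}

#' Simulate standardized volumes from a normal model
#'
#' Draws voxel-wise independent Gaussian volumes with the model's mean and
#' SD (clipped at 0), e.g. for null-calibration experiments.
#'
#' @param object a [normal_model].
#' @param nsim number of volumes.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return List of [suv_volume]s.
#' @export
simulate.normal_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$grid_shape
  lapply(seq_len(nsim), function(i) {
    x <- pmax(object$mean +
                array(stats::rnorm(prod(d)), d) * object$sd, 0)
    suv_volume(x, spacing = object$spacing, sex = object$sex,
               id = sprintf("sim-%d", i))
  })
}

#' Plot coronal sections of a normal model
#'
#' @param x a [normal_model].
#' @param y coronal slice index (defaults to the mid-grid slice).
#' @param ... passed to [graphics::image].
#' @export
plot.normal_model <- function(x, y = NULL, ...) {
  if (is.null(y)) y <- round(x$grid_shape[2] / 2)
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(x$mean[, y, ], main = sprintf("mean SUV (y = %d)", y),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::image(x$sd[, y, ], main = "SD",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
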