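# Normal-model persistence: a directory archive holding mean/SD/valid grids
# as NIfTI plus JSON metadata sidecars with a format version. Field order
# and float encoding are fixed so two saves of the same model are
# byte-identical. When the model carries a standard body, its landmarks,
# planes, surface control points and body mask are archived too, so a
# loaded model can standardize new scans.

.MODEL_FORMAT_VERSION <- "1.0"

.write_grid <- function(arr, spacing, path) {
  # float64 so the round trip is exact (SUV volumes elsewhere use float32)
  img <- RNifti::asNifti(arr, datatype = "double")
  img$pixdim <- c(-1, spacing, 0, 0, 0, 0)
  qf <- diag(c(spacing[1], -spacing[2], spacing[3], 1))
  attr(qf, "code") <- 2L
  RNifti::qform(img) <- qf
  RNifti::writeNifti(img, path)
}

#' Save a normal model
#'
#' Writes `path/` as a model archive: `mean.nii.gz`, `sd.nii.gz`,
#' `valid.nii.gz`, `model.json` (format version, case count, sex, grid
#' geometry) and, when present, the full standard body
#' (`standard.json` + `standard_mask.nii.gz`). Serialization is
#' deterministic: two saves of the same model produce byte-identical files.
#'
#' @param model a [normal_model].
#' @param path directory to create.
#' @param overwrite replace an existing archive.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, overwrite = FALSE) {
  stopifnot(inherits(model, "normal_model"))
  if (dir.exists(path) && length(dir(path)) > 0L && !overwrite)
    stop("'", path, "' exists and is not empty; use overwrite = TRUE",
         call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  .write_grid(model$mean, model$spacing, file.path(path, "mean.nii.gz"))
  .write_grid(model$sd, model$spacing, file.path(path, "sd.nii.gz"))
  .write_grid(array(as.numeric(model$valid), model$grid_shape),
              model$spacing, file.path(path, "valid.nii.gz"))
  meta <- list(format_version = .MODEL_FORMAT_VERSION,
               n = model$n, sex = model$sex,
               grid_shape = model$grid_shape,
               spacing = model$spacing,
               has_standard = !is.null(model$standard),
               software = "petnorm")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(path, "model.json"))
  if (!is.null(model$standard)) {
    std <- model$standard
    sj <- list(landmarks = unclass(std$landmarks),
               landmark_names = rownames(std$landmarks),
               planes = unclass(std$planes),
               surface_points = list(points = std$surface_points$points,
                                     level = std$surface_points$level,
                                     angle = std$surface_points$angle,
                                     angular_step = std$surface_points$angular_step,
                                     levels = std$surface_points$levels),
               grid_shape = std$grid_shape, spacing = std$spacing,
               sex = std$sex, id = std$id)
    writeLines(jsonlite::toJSON(sj, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(path, "standard.json"))
    .write_grid(array(as.numeric(std$body_mask$data), std$grid_shape),
                std$spacing, file.path(path, "standard_mask.nii.gz"))
  }
  invisible(path)
}

#' Load a normal model saved by [save_model]
#'
#' @param path model archive directory.
#' @return A [normal_model]; archives of a different format version raise an
#'   incompatibility error, truncated or unreadable files a corruption
#'   error (never a partial model).
#' @export
load_model <- function(path) {
  meta_file <- file.path(path, "model.json")
  if (!dir.exists(path) || !file.exists(meta_file))
    stop("'", path, "' is not a model archive (model.json missing)",
         call. = FALSE)
  meta <- tryCatch(jsonlite::fromJSON(meta_file),
                   error = function(e)
                     stop("corrupt model archive: unreadable model.json (",
                          conditionMessage(e), ")", call. = FALSE))
  if (is.null(meta$format_version) ||
      !identical(as.character(meta$format_version), .MODEL_FORMAT_VERSION))
    stop("incompatible model archive: format version '",
         meta$format_version %||% "<missing>", "' (this build reads ",
         .MODEL_FORMAT_VERSION, ")", call. = FALSE)
  rd <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f))
      stop("corrupt model archive: ", file, " missing", call. = FALSE)
    tryCatch({
      a <- as.array(RNifti::readNifti(f))
      attributes(a) <- list(dim = dim(a))
      a
    },
             error = function(e)
               stop("corrupt model archive: failed to read ", file, " (",
                    conditionMessage(e), ")", call. = FALSE))
  }
  M <- rd("mean.nii.gz"); S <- rd("sd.nii.gz"); Vd <- rd("valid.nii.gz")
  d <- as.integer(meta$grid_shape)
  if (!identical(dim(M), d) || !identical(dim(S), d) ||
      !identical(dim(Vd), d))
    stop("corrupt model archive: grid shape mismatch", call. = FALSE)
  std <- NULL
  if (isTRUE(meta$has_standard)) {
    sj <- tryCatch(jsonlite::fromJSON(file.path(path, "standard.json")),
                   error = function(e)
                     stop("corrupt model archive: unreadable standard.json",
                          call. = FALSE))
    lm <- as.matrix(sj$landmarks)
    dimnames(lm) <- list(sj$landmark_names, c("x", "y", "z"))
    class(lm) <- c("landmark_set", "matrix", "array")
    sp <- structure(list(points = as.matrix(sj$surface_points$points),
                         level = as.integer(sj$surface_points$level),
                         angle = as.numeric(sj$surface_points$angle),
                         angular_step = as.numeric(sj$surface_points$angular_step),
                         levels = as.integer(sj$surface_points$levels)),
                    class = "surface_points")
    dimnames(sp$points) <- NULL
    planes <- structure(lapply(sj$planes, as.numeric),
                        class = "torso_planes")
    bm <- rd("standard_mask.nii.gz")
    std <- structure(list(landmarks = lm, planes = planes,
                          surface_points = sp,
                          body_mask = binary_mask(bm > 0.5,
                                                  as.numeric(sj$spacing)),
                          grid_shape = as.integer(sj$grid_shape),
                          spacing = as.numeric(sj$spacing),
                          sex = sj$sex, id = sj$id %||% ""),
                     class = "standard_body")
  }
  structure(list(mean = M, sd = S, n = as.integer(meta$n),
                 sex = meta$sex, valid = array(Vd > 0.5, d),
                 grid_shape = d, spacing = as.numeric(meta$spacing),
                 standard = std),
            class = "normal_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
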