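#' SUV volume
#'
#' Container for a 3D grid of standardized uptake values (SUV). The axis
#' convention is fixed throughout the package: axis 1 runs patient
#' left-to-right (x), axis 2 anterior-to-posterior (y), axis 3
#' inferior-to-superior (z). Axial planes are fixed-z slices, coronal planes
#' fixed-y, sagittal planes fixed-x. Voxel indices are 1-based.
#'
#' @param data numeric 3D array of SUV values (dimensionless, finite, >= 0).
#' @param spacing numeric length-3 vector of voxel sizes in mm, all > 0.
#' @param sex one of `"male"`, `"female"`, `"unknown"`.
#' @param id scan identifier string.
#' @return An object of class `suv_volume` with elements `data`, `spacing`,
#'   `axes` (always `"RPS"`), `sex` and `id`.
#' @examples
#' v <- suv_volume(array(1, c(4, 4, 4)), spacing = c(4, 4, 4))
#' dim(v$data)
#' @export
suv_volume <- function(data, spacing = c(1, 1, 1),
                       sex = c("unknown", "male", "female"), id = "") {
  sex <- match.arg(sex)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions",
         call. = FALSE)
  if (any(dim(data) < 2L))
    stop("grid must have at least 2 voxels along each axis", call. = FALSE)
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("SUV values must all be finite", call. = FALSE)
  nneg <- sum(data < 0)
  if (nneg > 0L)
    stop("SUV values must be non-negative; ", nneg, " voxel(s) are negative",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel sizes in mm",
         call. = FALSE)
  structure(list(data = data, spacing = spacing, axes = "RPS",
                 sex = sex, id = as.character(id)[1L]),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("SUV volume", if (nzchar(x$id)) paste0("'", x$id, "'") else "", "\n")
  cat(sprintf("  grid    : %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing : %.3g x %.3g x %.3g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  sex     : %s\n", x$sex))
  cat(sprintf("  SUV     : [%.3g, %.3g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Read an SUV volume from a NIfTI file
#'
#' Reads a 3D NIfTI image and normalizes it to the package's internal axis
#' convention (x: left-to-right, y: anterior-to-posterior, z:
#' inferior-to-superior) using the file's qform/sform when present; files
#' without a usable xform are assumed to already follow the convention.
#' Voxel spacing is taken from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param sex sex tag to attach (not stored in NIfTI headers).
#' @param id scan identifier; defaults to the file name.
#' @return An [suv_volume].
#' @export
read_volume <- function(path, sex = c("unknown", "male", "female"), id = NULL) {
  sex <- match.arg(sex)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3D image, but '", path, "' has ", nd, " dimensions",
         call. = FALSE)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  hdr <- RNifti::niftiHeader(img)
  if (!is.na(orient) && (hdr$qform_code > 0L || hdr$sform_code > 0L) &&
      !identical(orient, "RPS")) {
    RNifti::orientation(img) <- "RPS"
  }
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  nneg <- sum(dat < 0)
  if (nneg > 0L)
    stop("'", path, "' contains ", nneg, " negative voxel(s); not a valid ",
         "SUV volume", call. = FALSE)
  suv_volume(dat, spacing = RNifti::pixdim(img), sex = sex,
             id = if (is.null(id)) basename(path) else id)
}

#' Write an SUV volume to a NIfTI file
#'
#' Values are stored as 32-bit floats. The qform encodes the internal "RPS"
#' axis convention so that [read_volume] round-trips the grid exactly at
#' stored precision.
#'
#' @param volume an [suv_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "suv_volume"))
  img <- RNifti::asNifti(volume$data, datatype = "float")
  img$pixdim <- c(-1, volume$spacing, 0, 0, 0, 0)
  qf <- diag(c(volume$spacing[1], -volume$spacing[2], volume$spacing[3], 1))
  attr(qf, "code") <- 2L
  RNifti::qform(img) <- qf
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert a raw activity volume to SUV
#'
#' Body-weight SUV: tissue activity concentration divided by injected dose
#' per gram of body mass, `SUV = A[kBq/mL] * mass[g] / dose[kBq]`
#' (assuming 1 g/mL tissue density), which simplifies to
#' `A * body_mass_kg / injected_dose_MBq`.
#'
#' @param activity numeric 3D array of activity concentration in kBq/mL.
#' @param injected_dose injected dose in MBq, > 0.
#' @param body_mass body mass in kg, > 0.
#' @param spacing,sex,id passed to [suv_volume].
#' @return An [suv_volume]; the normalization mode is recorded in the id-free
#'   attribute `normalization = "body_weight"`.
#' @examples
#' a <- array(3.5, c(4, 4, 4))
#' v <- suv_convert(a, injected_dose = 175, body_mass = 70)
#' v$data[1, 1, 1]  # 1.4
#' @export
suv_convert <- function(activity, injected_dose, body_mass,
                        spacing = c(1, 1, 1), sex = "unknown", id = "") {
  if (!is.numeric(injected_dose) || length(injected_dose) != 1L ||
      !is.finite(injected_dose) || injected_dose <= 0)
    stop("`injected_dose` must be a single positive value in MBq",
         call. = FALSE)
  if (!is.numeric(body_mass) || length(body_mass) != 1L ||
      !is.finite(body_mass) || body_mass <= 0)
    stop("`body_mass` must be a single positive value in kg", call. = FALSE)
  v <- suv_volume(activity * body_mass / injected_dose, spacing = spacing,
                  sex = sex, id = id)
  attr(v, "normalization") <- "body_weight"
  v
}
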