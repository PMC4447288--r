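test_that("NIfTI write/read round-trips grid and spacing", {
  vol <- tp_phantom0$volume
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, sex = vol$sex)
  # values are stored as float32: exact for the phantom's dyadic organ SUVs,
  # within single precision otherwise
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_identical(back$spacing, vol$spacing)
  # a second round trip of the float32-quantized data is bitwise exact
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(back, f2)
  expect_identical(read_volume(f2)$data, back$data)
})

test_that("anisotropic header spacing is reported exactly", {
  # header written by the NIfTI library directly, not by write_volume
  a <- array(runif(6 * 6 * 6), c(6, 6, 6))
  img <- RNifti::asNifti(a, datatype = "float")
  img$pixdim <- c(-1, 4, 4, 4.25, 0, 0, 0, 0)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  v <- read_volume(f)
  expect_identical(v$spacing, c(4, 4, 4.25))
})

test_that("files in another orientation are normalized on read", {
  a <- array(0, c(6, 7, 8)); a[2, 3, 4] <- 5
  img <- RNifti::asNifti(a, datatype = "float")
  img$pixdim <- c(-1, 2, 2, 2, 0, 0, 0, 0)
  qf <- diag(c(-2, -2, 2, 1))   # "LPS": x axis stored right-to-left
  attr(qf, "code") <- 2L
  RNifti::qform(img) <- qf
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  v <- read_volume(f)
  expect_equal(dim(v$data), c(6L, 7L, 8L))
  expect_equal(v$data[6 - 2 + 1, 3, 4], 5)  # x flipped into L-to-R order
})

test_that("non-3D and invalid files are rejected", {
  a4 <- array(1, c(4, 4, 4, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(a4, datatype = "float"), f)
  expect_error(read_volume(f), "3D")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  aneg <- array(1, c(4, 4, 4)); aneg[1:3] <- -1
  fn <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(aneg, datatype = "float"), fn)
  expect_error(read_volume(fn), "3 negative voxel")
})

test_that("suv_volume validates its invariants", {
  expect_error(suv_volume(array(1, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(suv_volume(array(1, c(1, 4, 4))), "at least 2")
  expect_error(suv_volume(array(-1, c(4, 4, 4))), "negative")
  expect_error(suv_volume(array(Inf, c(4, 4, 4))), "finite")
  expect_error(suv_volume(array(1, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("SUV conversion follows the body-weight definition", {
  a <- array(3.5, c(4, 4, 4))
  v <- suv_convert(a, injected_dose = 175, body_mass = 70)
  expect_equal(v$data, array(1.4, c(4, 4, 4)))
  # activity equal to dose per gram of body mass gives SUV 1
  u <- suv_convert(array(175 / 70, c(4, 4, 4)), 175, 70)
  expect_equal(u$data, array(1, c(4, 4, 4)))
  # zero activity maps to zero SUV
  expect_equal(suv_convert(array(0, c(4, 4, 4)), 175, 70)$data,
               array(0, c(4, 4, 4)))
  # linear in activity, inversely linear in dose
  v2 <- suv_convert(2 * a, 175, 70)
  expect_equal(v2$data, 2 * v$data)
  v3 <- suv_convert(a, 2 * 175, 70)
  expect_equal(v3$data, v$data / 2)
  expect_error(suv_convert(a, -1, 70), "positive")
  expect_error(suv_convert(a, 175, 0), "positive")
})
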