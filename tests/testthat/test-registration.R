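mk_planes <- function(ns, th, bl, lv, xl, xr, ya, yp)
  torso_planes(ns_z = ns, th_z = th, bl_z = bl, lv_z = lv,
               ac_left_x = xl, ac_right_x = xr, a_y = ya, p_y = yp)

test_that("cuboid map fixes all 16 corners and is continuous across slabs", {
  src <- assemble_landmarks(mk_planes(100, 20, 38, 72, 12, 52, 14, 44))
  dst <- assemble_landmarks(mk_planes(54, 14, 19, 42, 11, 54, 20, 45))
  mapped <- map_cuboid_points(unclass(src), src, dst)
  expect_equal(mapped, unclass(dst), ignore_attr = TRUE, tolerance = 1e-12)
  # continuity at the BL and LV planes: approach from both slabs
  eps <- 1e-9
  for (zb in c(38, 72)) {
    probes <- cbind(runif(20, 12, 52), runif(20, 14, 44), zb)
    lo <- map_cuboid_points(sweep(probes, 2, c(0, 0, eps)), src, dst)
    hi <- map_cuboid_points(sweep(probes, 2, c(0, 0, -eps)), src, dst)
    expect_lt(max(abs(lo - hi)), 1e-7)
  }
})

test_that("cuboid resampling is the identity when src equals dst", {
  lm <- tp_std$landmarks
  out <- map_cuboid(tp_phantom0$volume, lm, lm)
  expect_identical(out$data, tp_phantom0$volume$data)
})

test_that("cuboid mapping aligns a scaled subject's liver plane", {
  subj <- phantom_population(phantom_config(noise_sd = 0), 2,
                             seed = 21)[[2]]
  det <- detect_torso_planes(subj$volume, tp_cfg)
  warped <- map_cuboid(subj$volume, det$landmarks, tp_std$landmarks,
                       out_shape = tp_std$grid_shape,
                       out_spacing = tp_std$spacing)
  det2 <- detect_torso_planes(warped, tp_cfg)
  expect_lte(abs(det2$planes$lv_z - tp_std$planes$lv_z), 1)
  expect_lte(abs(det2$planes$ns_z - tp_std$planes$ns_z), 1)
})

test_that("surface points sit on analytic circle and ellipse boundaries", {
  d <- c(64, 64, 8)
  circ <- array(FALSE, d)
  X <- matrix(seq_len(64), 64, 64); Y <- t(X)
  circ[, , 3] <- (X - 32)^2 + (Y - 32)^2 <= 20^2
  circ[, , 6] <- (X - 32)^2 + (Y - 32)^2 <= 20^2
  m <- binary_mask(circ, c(4, 4, 4))
  sp <- place_surface_points(m, levels = 3, angular_step = 15)
  expect_equal(nrow(sp$points), 24L)
  r <- sqrt((sp$points[, 1] - 32)^2 + (sp$points[, 2] - 32)^2)
  expect_true(all(abs(r - 20) <= 1))
  ell <- array(FALSE, d)
  ell[, , 3] <- ((X - 32) / 30)^2 + ((Y - 32) / 15)^2 <= 1
  spe <- place_surface_points(binary_mask(ell, c(4, 4, 4)), 3, 15)
  at0 <- spe$points[spe$angle == 0, ]
  at90 <- spe$points[spe$angle == 90, ]
  expect_lte(abs(at0[1] - 32 - 30), 1)
  expect_lte(abs(at90[2] - 32 - 15), 1)
  # two levels: 48 points, level-major angle-minor ordering
  sp2 <- place_surface_points(m, levels = c(3, 6), angular_step = 15)
  expect_equal(nrow(sp2$points), 48L)
  expect_equal(sp2$level, rep(c(3L, 6L), each = 24))
  expect_equal(sp2$angle[1:3], c(0, 15, 30))
  expect_error(place_surface_points(m, levels = c(3, 4)), "z=4")
})

test_that("TPS at lambda 0 interpolates exactly and reproduces affines", {
  set.seed(7)
  src <- cbind(runif(40, 5, 60), runif(40, 5, 60), runif(40, 5, 60))
  # identity correspondence
  id <- fit_tps(src, src)
  expect_lt(max(abs(id$weights)), 1e-8)
  expect_equal(id$affine, rbind(0, diag(3)), ignore_attr = TRUE,
               tolerance = 1e-8)
  # exact interpolation of arbitrary targets
  dst <- src + matrix(rnorm(120, 0, 3), 40, 3)
  tps <- fit_tps(src, dst)
  expect_lt(max(abs(predict(tps, src) - dst)), 1e-6)
  # side conditions on the kernel weights
  expect_lt(max(abs(colSums(tps$weights))), 1e-6)
  expect_lt(max(abs(crossprod(src, tps$weights))), 1e-4)
  # a known affine map is reproduced everywhere, not just at anchors
  A <- matrix(c(1.1, 0.05, 0, -0.02, 0.95, 0.03, 0, 0.01, 1.2), 3, 3)
  b <- c(2, -1, 3)
  tps_a <- fit_tps(src, t(A %*% t(src) + b))
  expect_lt(max(abs(tps_a$weights)), 1e-6)
  probes <- cbind(runif(100, 0, 70), runif(100, 0, 70), runif(100, 0, 70))
  expect_lt(max(abs(predict(tps_a, probes) - t(A %*% t(probes) + b))),
            1e-5)
})

test_that("TPS anchor residual grows monotonically with lambda", {
  set.seed(11)
  src <- cbind(runif(30, 5, 60), runif(30, 5, 60), runif(30, 5, 60))
  dst <- src + matrix(rnorm(90, 0, 2), 30, 3)
  resid <- vapply(c(0, 1, 10, 100), function(l) {
    tps <- fit_tps(src, dst, lambda = l)
    max(abs(predict(tps, src) - dst))
  }, 0)
  expect_true(all(diff(resid) > 0))
  expect_lt(resid[1], 1e-6)
})

test_that("degenerate anchor configurations raise a solver error", {
  src <- cbind(runif(20, 5, 60), runif(20, 5, 60), 10)  # coplanar
  dst <- src + 1
  expect_error(fit_tps(src, dst), "singular|degenerate")
})

test_that("surface point tag mismatches are rejected", {
  body <- binary_mask(tp_phantom0$truth$body_mask,
                      tp_phantom0$volume$spacing)
  a <- place_surface_points(body, c(20, 30), 30)
  b <- place_surface_points(body, c(20, 40), 30)
  expect_error(fit_tps(a, b), "tags")
})

test_that("nearest-neighbor resampling translates and never invents values", {
  vol <- tp_phantom0$volume
  # pure translation fitted as a TPS (affine part reproduces it exactly)
  set.seed(3)
  anchors <- cbind(runif(30, 5, 60), runif(30, 5, 60), runif(30, 5, 60))
  tps <- fit_tps(anchors, sweep(anchors, 2, c(3, 0, 0)))  # out -> src: p - 3
  out <- resample_nn(vol, tps)
  d <- dim(vol$data)
  # output voxel x takes source voxel x - 3: compare on the overlap
  expect_equal(out$data[4:d[1], , ], vol$data[1:(d[1] - 3), , ])
  expect_true(all(out$data[1:3, , ] == 0))
  expect_true(all(out$data %in% c(0, vol$data)))
  # identity transform: exact copy
  expect_identical(resample_nn(vol, NULL)$data, vol$data)
  # a mild random warp still never invents intensities
  warp <- fit_tps(anchors, anchors + matrix(rnorm(90, 0, 1.5), 30, 3))
  wout <- resample_nn(vol, warp)
  expect_true(all(wout$data %in% c(0, vol$data)))
})

test_that("self-standardization is the identity up to resampling", {
  res <- standardize(tp_phantom0$volume, tp_std, tp_cfg)
  expect_equal(mean(abs(res$volume$data - tp_phantom0$volume$data)), 0)
  expect_lt(res$report$tps_max_anchor_residual, 1e-9)
  expect_equal(plane_vec(res$report$planes),
               plane_vec(tp_std$planes))
})

test_that("standardization refuses a sex mismatch", {
  phf <- generate_phantom(phantom_config(sex = "female", noise_sd = 0))
  expect_error(standardize(phf$volume, tp_std, tp_cfg), "sex mismatch")
})

test_that("global affine slab mode runs and roughly centers the subject", {
  subj <- phantom_population(phantom_config(noise_sd = 0), 1, seed = 5)[[1]]
  cfgg <- pet_config(slab_mode = "global")
  res <- standardize(subj$volume, tp_std, cfgg)
  expect_equal(res$report$slab_mode, "global")
  det <- detect_torso_planes(res$volume, tp_cfg)
  expect_lte(abs(det$planes$ns_z - tp_std$planes$ns_z), 3)
})
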