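test_that("detected planes match phantom ground truth", {
  det <- detect_torso_planes(tp_phantom0$volume, tp_cfg)
  tru <- plane_vec(tp_phantom0$truth$plane_truth)
  got <- plane_vec(det$report$planes)
  # axial and coronal planes are exact on a noiseless phantom; the AC
  # planes land anywhere in the (few-voxel) axilla air gap
  expect_equal(got[c("ns_z", "th_z", "bl_z", "lv_z", "a_y", "p_y")],
               tru[c("ns_z", "th_z", "bl_z", "lv_z", "a_y", "p_y")])
  expect_lte(abs(got["ac_left_x"] - tru["ac_left_x"]), 1)
  expect_lte(abs(got["ac_right_x"] - tru["ac_right_x"]), 1)
  expect_false(det$report$bl_fallback)
})

test_that("NS ties break toward the superior slice and edges are safe", {
  # constant-area cylinder: every slice ties, the most superior wins
  cyl <- array(FALSE, c(20, 20, 30))
  for (z in 3:28) cyl[6:15, 6:15, z] <- TRUE
  m <- binary_mask(cyl, c(4, 4, 4))
  expect_equal(detect_ns_plane(m, band_frac = 0.35), 28)
  # torso reaching the grid top: returns the top slice, no crash
  cyl2 <- array(FALSE, c(20, 20, 30))
  for (z in 3:30) cyl2[6:15, 6:15, z] <- TRUE
  expect_equal(detect_ns_plane(binary_mask(cyl2, c(4, 4, 4))), 30)
})

test_that("AC detection mirrors under x flip and fails without arms", {
  body <- binary_mask(tp_phantom0$truth$body_mask,
                      tp_phantom0$volume$spacing)
  ac <- detect_ac_planes(body)
  flipped <- binary_mask(body$data[dim(body$data)[1]:1, , ],
                         body$spacing)
  acf <- detect_ac_planes(flipped)
  n <- dim(body$data)[1]
  expect_equal(unname(acf["left"]), n + 1 - unname(ac["right"]))
  expect_equal(unname(acf["right"]), n + 1 - unname(ac["left"]))
  # armless phantom: unimodal profile, explicit no-axilla diagnosis
  pha <- generate_phantom(phantom_config(noise_sd = 0, arms = FALSE))
  expect_true(is.na(pha$truth$plane_truth$ac_left_x))
  ba <- binary_mask(pha$truth$body_mask, pha$volume$spacing)
  expect_error(detect_ac_planes(ba), "axilla")
})

test_that("TH detection ignores small specks and fails when cropped", {
  body <- tp_phantom0$truth$body_mask
  th <- detect_th_plane(binary_mask(body, c(4, 4, 4)))
  expect_equal(th, tp_phantom0$truth$plane_truth$th_z)
  # 3-voxel speck between the thighs on a thigh slice: unchanged
  speck <- body
  zthigh <- th - 3
  speck[32:34, 33, zthigh] <- TRUE
  expect_equal(detect_th_plane(binary_mask(speck, c(4, 4, 4))), th)
  # cropped above the thighs: never two-then-one large components
  cropped <- body
  cropped[, , th:dim(body)[3]] <- FALSE
  expect_error(detect_th_plane(binary_mask(cropped, c(4, 4, 4))),
               "never unite")
})

test_that("A/P planes exclude a protruding head", {
  ph <- generate_phantom(phantom_config(noise_sd = 0, head_y_offset = -7))
  body <- ph$truth$body_mask
  ns <- ph$truth$plane_truth$ns_z
  ap <- detect_ap_planes(binary_mask(body, c(4, 4, 4)), ns)
  # oracle: coronal profiles with and without the head differ
  with_head <- min(which(apply(body, 2, sum) > 0))
  below_ns <- apply(body[, , seq_len(ns), drop = FALSE], 2, sum)
  without_head <- min(which(below_ns > 0))
  expect_lt(with_head, without_head)   # the head does protrude
  expect_equal(unname(ap["a"]), without_head)
  expect_equal(unname(ap["p"]), max(which(below_ns > 0)))
})

test_that("BL plane is the mean of per-label coronal centroids", {
  d <- c(30, 30, 30)
  one <- array(FALSE, d); one[15, 15, 20] <- TRUE
  expect_equal(compute_bl_plane(binary_mask(one, c(4, 4, 4))), 20L)
  two <- array(FALSE, d)
  two[10:12, 15, 10] <- TRUE    # label at z = 10
  two[10:12, 15, 14] <- TRUE    # equal label at z = 14
  expect_equal(compute_bl_plane(binary_mask(two, c(4, 4, 4))), 12L)
  expect_error(compute_bl_plane(binary_mask(array(FALSE, d), c(4, 4, 4))),
               "empty")
})

test_that("LV plane is the liver apex and shifts equivariantly", {
  d <- c(30, 30, 30)
  one <- array(FALSE, d); one[15, 15, 17] <- TRUE
  expect_equal(compute_lv_plane(binary_mask(one, c(4, 4, 4))), 17L)
  liv <- tp_phantom0$truth$organ_masks$liver
  lv0 <- compute_lv_plane(binary_mask(liv, c(4, 4, 4)))
  shifted <- array(FALSE, dim(liv))
  shifted[, , 6:dim(liv)[3]] <- liv[, , 1:(dim(liv)[3] - 5)]
  expect_equal(compute_lv_plane(binary_mask(shifted, c(4, 4, 4))), lv0 + 5)
})

test_that("landmark assembly enumerates the cuboid corner product", {
  pl <- torso_planes(ns_z = 90, th_z = 25, bl_z = 40, lv_z = 70,
                     ac_left_x = 10, ac_right_x = 50, a_y = 12, p_y = 40)
  lm <- assemble_landmarks(pl)
  expect_equal(nrow(lm), 16L)
  expect_equal(unname(lm["S1", ]), c(10, 12, 90))
  # independent enumeration: the point set is exactly the Cartesian product
  prod_pts <- as.matrix(expand.grid(x = c(10, 50), y = c(12, 40),
                                    z = c(90, 70, 40, 25)))
  expect_equal(nrow(unique(rbind(unclass(lm)[, 1:3], prod_pts))), 16L)
  # per-level and face structure
  expect_true(all(lm[c("S1", "S2", "S3", "S4"), "z"] == 90))
  expect_true(all(lm[c("T1", "T2", "T3", "T4"), "z"] == 25))
  expect_true(all(lm[c("S1", "S2", "T2", "T1"), "y"] == 12))  # anterior face
  expect_true(all(lm[c("S1", "T1", "T4", "S4"), "x"] == 10))  # left face
  # degenerate plane orderings are rejected
  expect_error(torso_planes(90, 25, 40, 40, 10, 50, 12, 40), "ordered")
  expect_error(torso_planes(90, 25, 40, 70, 50, 10, 12, 40), "left")
})
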