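test_that("noiseless phantom paints exact organ SUVs", {
  ph <- tp_phantom0
  cfg <- ph$truth$config
  v <- ph$volume$data
  for (organ in names(ph$truth$organ_masks)) {
    m <- ph$truth$organ_masks[[organ]]
    expect_true(all(v[m] == cfg$organ_suv[organ]),
                label = paste("uniform SUV in", organ))
  }
  # body mask is exactly the support of the noiseless image
  expect_identical(ph$truth$body_mask, v > 0)
  # voxel max equals the hottest configured structure
  expect_equal(max(v), unname(max(cfg$organ_suv)))
})

test_that("phantom generation is deterministic", {
  cfg <- phantom_config(noise_sd = 0.2, seed = 33)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$plane_truth, b$truth$plane_truth)
})

test_that("NS truth is the brute-force minimum-area slice", {
  body <- tp_phantom0$truth$body_mask
  areas <- vapply(seq_len(dim(body)[3]), function(z) sum(body[, , z]), 0)
  nz <- which(areas > 0)
  cand <- nz[areas[nz] == min(areas[nz])]
  expect_equal(tp_phantom0$truth$plane_truth$ns_z, max(cand))
})

test_that("phantom truth planes are inside the grid and ordered", {
  tr <- tp_phantom0$truth$plane_truth
  expect_true(tr$th_z < tr$bl_z && tr$bl_z < tr$lv_z && tr$lv_z < tr$ns_z)
  d <- dim(tp_phantom0$volume$data)
  expect_true(all(plane_vec(tr) >= 1))
  expect_true(tr$ns_z <= d[3] && tr$ac_right_x <= d[1] && tr$p_y <= d[2])
  # every lesion-free landmark lies on the cuboid hull
  lm <- tp_phantom0$truth$landmark_truth
  expect_equal(nrow(unique(unclass(lm))), 16L)
})

test_that("lesions must lie inside the body; planted lesions are recorded", {
  out_center <- c(2, 2, 32)   # air
  expect_error(generate_phantom(phantom_config(noise_sd = 0,
    lesions = list(list(center = out_center, radius = 10, suv = 5)))),
    "outside the body")
  les <- list(center = c(24, 33, 28), radius = 12, suv = 5)
  ph <- generate_phantom(phantom_config(noise_sd = 0, lesions = list(les)))
  rec <- ph$truth$lesion_records[[1]]
  expect_equal(rec$suv, 5)
  expect_true(all(ph$volume$data[rec$mask] == 5))
  expect_equal(max(ph$volume$data), 12)  # bladder still hottest
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(torso_width_scale = 2.5), "scales")
  expect_error(phantom_config(organ_suv = c(soft = 1, lung = 0.6,
    liver = 2, brain = 7, bladder = 0.9)), "bladder SUV")
  expect_error(phantom_population(phantom_config(), 0), ">= 1")
})

test_that("cohorts are reproducible and jitter around configured centers", {
  base <- phantom_config(noise_sd = 0)
  a <- phantom_population(base, 6, seed = 9)
  b <- phantom_population(base, 6, seed = 9)
  for (i in seq_along(a))
    expect_identical(a[[i]]$volume$data, b[[i]]$volume$data)
  # n = 1 equals a single generate_phantom of the jittered config
  one <- phantom_population(base, 1, seed = 9)
  expect_identical(one[[1]]$volume$data,
                   generate_phantom(one[[1]]$truth$config)$volume$data)
  # Monte-Carlo: mean per-subject liver SUV across a cohort sits within
  # 3 standard errors of the configured center (uniform(0.9, 1.1) jitter)
  pop <- phantom_population(base, 50, seed = 17)
  liver_suv <- vapply(pop, function(ph)
    mean(ph$volume$data[ph$truth$organ_masks$liver]), 0)
  center <- base$organ_suv[["liver"]]
  se <- center * (0.2 / sqrt(12)) / sqrt(50)
  expect_lt(abs(mean(liver_suv) - center), 3 * se)
})
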