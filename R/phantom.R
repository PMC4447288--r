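#' Configuration for a synthetic torso phantom
#'
#' The phantom is a stack of elliptical axial cross-sections forming thighs,
#' hips, waist, chest with separated arms, shoulders, a neck with a distinct
#' area minimum, and a head, so that every rule-based plane detector in the
#' pipeline has a well-defined answer. Ellipsoidal organs (brain, lungs,
#' liver, bladder) are painted with configurable mean SUVs; the bladder SUV
#' must exceed soft tissue, since tracer excreted in urine makes the bladder
#' the high-contrast structure the bladder-plane detector presumes.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing voxel size in mm.
#' @param sex `"male"` or `"female"`; females are generated slightly
#'   narrower and shorter.
#' @param torso_height_scale,torso_width_scale,torso_depth_scale physique
#'   multipliers, each in (0.5, 2).
#' @param organ_suv named numeric vector of mean SUVs for `soft`, `lung`,
#'   `liver`, `brain`, `bladder`.
#' @param noise_sd SD of additive Gaussian noise in SUV units (clipped at 0);
#'   0 gives an exact noiseless phantom.
#' @param lesions list of lesions, each `list(center = c(x, y, z) voxel
#'   indices, radius = mm, suv = value)`.
#' @param head_y_offset anterior (negative) / posterior shift of head and
#'   brain in voxels, for head-exclusion tests.
#' @param arms if `FALSE` the phantom is generated armless (the arms-chest
#'   plane detector must then fail with a no-axilla diagnosis).
#' @param seed integer seed; identical configs and seeds give identical
#'   phantoms.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           spacing = c(6, 6, 10),
                           sex = c("male", "female"),
                           torso_height_scale = 1,
                           torso_width_scale = 1,
                           torso_depth_scale = 1,
                           organ_suv = c(soft = 1.0, lung = 0.6, liver = 2.0,
                                         brain = 7.0, bladder = 12.0),
                           noise_sd = 0.1,
                           lesions = list(),
                           head_y_offset = 0,
                           arms = TRUE,
                           seed = 1L) {
  sex <- match.arg(sex)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            length(spacing) == 3L, all(spacing > 0))
  sc <- c(torso_height_scale, torso_width_scale, torso_depth_scale)
  if (any(sc <= 0.5) || any(sc >= 2.0))
    stop("physique scales must lie in (0.5, 2.0)", call. = FALSE)
  need <- c("soft", "lung", "liver", "brain", "bladder")
  if (!all(need %in% names(organ_suv)))
    stop("`organ_suv` must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  organ_suv <- organ_suv[need]
  if (any(organ_suv < 0)) stop("organ SUVs must be >= 0", call. = FALSE)
  if (organ_suv["bladder"] <= organ_suv["soft"])
    stop("bladder SUV must exceed soft-tissue SUV (the bladder-plane ",
         "detector presumes urinary tracer contrast)", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 sex = sex,
                 torso_height_scale = torso_height_scale,
                 torso_width_scale = torso_width_scale,
                 torso_depth_scale = torso_depth_scale,
                 organ_suv = organ_suv, noise_sd = noise_sd,
                 lesions = lesions, head_y_offset = head_y_offset,
                 arms = isTRUE(arms), seed = as.integer(seed)),
            class = "phantom_config")
}

# per-slice body geometry: list of ellipses (cx, cy, ax, ay) for one axial
# slice at body-height fraction f (0 = soles of the generated segment,
# 1 = top of head)
.phantom_slices <- function(cfg) {
  d <- cfg$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  sexw <- if (cfg$sex == "female") 0.90 else 1.0
  sexh <- if (cfg$sex == "female") 0.94 else 1.0
  ws <- cfg$torso_width_scale * sexw
  ds <- cfg$torso_depth_scale * sexw
  H <- round(0.92 * nz * cfg$torso_height_scale * sexh)
  H <- min(H, nz - 3L)
  zb0 <- 2L                       # first body slice
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2 + 0
  slices <- vector("list", nz)
  for (z in seq_len(nz)) {
    f <- (z - zb0) / H
    if (f < 0 || f > 1) { slices[[z]] <- list(); next }
    ell <- list()
    add <- function(cxe, cye, axe, aye)
      ell[[length(ell) + 1L]] <<- c(cx = cxe, cy = cye, ax = axe, ay = aye)
    if (f < 0.20) {                               # two thighs
      add(cx - 0.145 * nx * ws, cy, 0.105 * nx * ws, 0.14 * ny * ds)
      add(cx + 0.145 * nx * ws, cy, 0.105 * nx * ws, 0.14 * ny * ds)
    } else if (f < 0.35) {                        # hips
      add(cx, cy, 0.28 * nx * ws, 0.20 * ny * ds)
    } else if (f < 0.50) {                        # waist
      add(cx, cy, 0.25 * nx * ws, 0.18 * ny * ds)
    } else if (f < 0.78) {                        # chest
      add(cx, cy, 0.30 * nx * ws, 0.20 * ny * ds)
    } else if (f < 0.85) {                        # shoulders
      add(cx, cy, 0.42 * nx * ws, 0.16 * ny * ds)
    } else if (f < 0.92) {                        # neck: unique area minimum
      u <- (f - 0.885) / 0.035                    # -1..1 across the band
      r <- 0.095 - 0.025 * (1 - min(1, u^2))
      add(cx, cy, r * nx * ws, r * ny * ds)
    } else {                                      # head
      add(cx, cy + cfg$head_y_offset, 0.13 * nx * ws, 0.13 * ny * ds)
    }
    if (cfg$arms && f >= 0.35 && f < 0.80) {      # arms beside the chest
      add(cx - 0.40 * nx * ws, cy, 0.045 * nx * ws, 0.05 * ny * ds)
      add(cx + 0.40 * nx * ws, cy, 0.045 * nx * ws, 0.05 * ny * ds)
    }
    slices[[z]] <- ell
  }
  list(slices = slices, H = H, zb0 = zb0, cx = cx, cy = cy,
       ws = ws, ds = ds)
}

.paint_ellipse <- function(mask_slice, e, X, Y) {
  inside <- ((X - e["cx"]) / e["ax"])^2 + ((Y - e["cy"]) / e["ay"])^2 <= 1
  mask_slice | inside
}

.ellipsoid_mask <- function(d, center, semi) {
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  dx2 <- ((x - center[1]) / semi[1])^2
  dy2 <- ((y - center[2]) / semi[2])^2
  dz2 <- ((z - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Generate a synthetic torso SUV phantom with ground truth
#'
#' @param config a [phantom_config].
#' @return A list with elements `volume` (an [suv_volume]) and `truth`, a
#'   `phantom_truth` list carrying `body_mask`, `organ_masks` (mutually
#'   exclusive masks for brain, lung, liver, bladder), `plane_truth`
#'   (ns_z, ac_left_x, ac_right_x, th_z, a_y, p_y, bl_z, lv_z),
#'   `landmark_truth` (16 named corner points) and `lesion_records`.
#'   Plane truths are computed from the noiseless geometry by definitional
#'   brute-force scans (area minima, profile minima, component counts).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  d <- cfg$grid_shape
  geom <- .phantom_slices(cfg)
  X <- matrix(seq_len(d[1]), d[1], d[2])
  Y <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  body <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    ell <- geom$slices[[z]]
    if (length(ell) == 0L) next
    sl <- matrix(FALSE, d[1], d[2])
    for (e in ell) sl <- .paint_ellipse(sl, e, X, Y)
    body[, , z] <- sl
  }

  H <- geom$H; zb0 <- geom$zb0
  nx <- d[1]; ny <- d[2]
  cx <- geom$cx; cy <- geom$cy; ws <- geom$ws; ds <- geom$ds
  zf <- function(f) zb0 + f * H
  organ_defs <- list(
    brain   = list(center = c(cx, cy + cfg$head_y_offset, zf(0.96)),
                   semi = c(0.085 * nx * ws, 0.085 * ny * ds, 0.035 * H)),
    lung_l  = list(center = c(cx - 0.13 * nx * ws, cy - 0.04 * ny * ds,
                              zf(0.70)),
                   semi = c(0.085 * nx * ws, 0.10 * ny * ds, 0.085 * H)),
    lung_r  = list(center = c(cx + 0.13 * nx * ws, cy - 0.04 * ny * ds,
                              zf(0.70)),
                   semi = c(0.085 * nx * ws, 0.10 * ny * ds, 0.085 * H)),
    liver   = list(center = c(cx + 0.14 * nx * ws, cy + 0.02 * ny * ds,
                              zf(0.60)),
                   semi = c(0.12 * nx * ws, 0.12 * ny * ds, 0.085 * H)),
    bladder = list(center = c(cx, cy + 0.03 * ny * ds, zf(0.295)),
                   semi = c(0.06 * nx * ws, 0.06 * ny * ds, 0.045 * H))
  )
  organ_of <- c(brain = "brain", lung_l = "lung", lung_r = "lung",
                liver = "liver", bladder = "bladder")
  # paint order: later organs overwrite earlier ones (liver apex carves the
  # lung base, as the diaphragm dome does)
  suv <- array(0, d)
  suv[body] <- cfg$organ_suv["soft"]
  masks <- list(brain = array(FALSE, d), lung = array(FALSE, d),
                liver = array(FALSE, d), bladder = array(FALSE, d))
  for (nm in c("lung_l", "lung_r", "liver", "brain", "bladder")) {
    om <- .ellipsoid_mask(d, organ_defs[[nm]]$center,
                          organ_defs[[nm]]$semi) & body
    for (other in names(masks)) masks[[other]] <- masks[[other]] & !om
    masks[[organ_of[nm]]] <- masks[[organ_of[nm]]] | om
    suv[om] <- cfg$organ_suv[organ_of[nm]]
  }

  # lesions: spheres, SUV takes the max of lesion and background
  lesion_records <- list()
  for (les in cfg$lesions) {
    ctr <- les$center
    if (!body[ctr[1], ctr[2], ctr[3]])
      stop("lesion center (", paste(ctr, collapse = ", "),
           ") lies outside the body", call. = FALSE)
    rad_vox <- les$radius / cfg$spacing
    lm <- .ellipsoid_mask(d, ctr, pmax(rad_vox, 0.5)) & body
    suv[lm] <- pmax(suv[lm], les$suv)
    lesion_records[[length(lesion_records) + 1L]] <-
      list(center = ctr, radius = les$radius, suv = les$suv, mask = lm)
  }

  plane_truth <- .phantom_plane_truth(body, masks, organ_defs,
                                      geom = if (cfg$arms) geom else NULL)
  landmark_truth <- if (!anyNA(unlist(plane_truth))) {
    assemble_landmarks(do.call(torso_planes,
      c(plane_truth, list(grid_shape = d))))
  } else NULL

  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    suv <- pmax(suv + array(stats::rnorm(prod(d), 0, cfg$noise_sd), d), 0)
  }

  vol <- suv_volume(suv, spacing = cfg$spacing, sex = cfg$sex,
                    id = sprintf("phantom-%s-seed%d", cfg$sex, cfg$seed))
  truth <- structure(list(body_mask = body, organ_masks = masks,
                          plane_truth = plane_truth,
                          landmark_truth = landmark_truth,
                          lesion_records = lesion_records,
                          config = cfg),
                     class = "phantom_truth")
  list(volume = vol, truth = truth)
}

# definitional brute-force plane truths on the noiseless body mask
.phantom_plane_truth <- function(body, masks, organ_defs, geom = NULL) {
  d <- dim(body)
  area <- apply(body, 3L, sum)
  nz_slices <- which(area > 0)
  # NS: global minimum-area nonzero slice, ties toward superior
  mins <- nz_slices[area[nz_slices] == min(area[nz_slices])]
  ns_z <- max(mins)
  # AC truth is analytic: the center of the designed arm-chest air gap
  # (between the chest ellipse edge and the inner arm edge)
  if (is.null(geom)) {
    left <- NA_integer_; right <- NA_integer_
  } else {
    gap_in <- 0.30 * d[1] * geom$ws      # chest half-width
    gap_out <- (0.40 - 0.045) * d[1] * geom$ws  # inner arm edge
    left <- as.integer(floor(geom$cx - (gap_in + gap_out) / 2 + 0.5))
    right <- as.integer(floor(geom$cx + (gap_in + gap_out) / 2 + 0.5))
  }
  # TH: scanning tail-to-head, first slice with one large component after
  # slices with two large components
  th_z <- NA_integer_
  seen_two <- FALSE
  for (z in nz_slices) {
    L <- label_components(body[, , z])
    sizes <- tabulate(L[L > 0])
    nlarge <- sum(sizes >= 50)
    if (nlarge == 2L) seen_two <- TRUE
    if (seen_two && nlarge == 1L) { th_z <- z; break }
  }
  # A/P: coronal profile over slices at or below NS (head excluded)
  sub <- body[, , seq_len(ns_z), drop = FALSE]
  yprof <- apply(sub, 2L, sum)
  a_y <- min(which(yprof > 0)); p_y <- max(which(yprof > 0))
  # BL: bladder ellipsoid centroid z; LV: liver apex z
  bl_z <- floor(mean(which(masks$bladder, arr.ind = TRUE)[, 3]) + 0.5)
  lv_z <- max(which(masks$liver, arr.ind = TRUE)[, 3])
  list(ns_z = ns_z, th_z = th_z, bl_z = bl_z, lv_z = lv_z,
       ac_left_x = left, ac_right_x = right, a_y = a_y, p_y = p_y)
}

#' Generate a reproducible phantom cohort
#'
#' Emulates a normal-database population: each subject draws physique scale
#' multipliers from uniform(0.9, 1.1) around the base config, multiplicative
#' organ-SUV jitter from uniform(0.9, 1.1), and a wide multiplicative bladder
#' jitter from uniform(2/3, 4/3) -- urinary filling varies far more between
#' subjects than parenchymal uptake, which is what makes high bladder SUV a
#' low Z-score structure.
#'
#' @param base a [phantom_config]; its scales and organ SUVs are jitter
#'   centers.
#' @param n number of subjects, >= 1.
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @return List of `n` phantoms as returned by [generate_phantom].
#' @export
phantom_population <- function(base, n, seed = 1L) {
  stopifnot(inherits(base, "phantom_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  subj_seed <- sample.int(.Machine$integer.max - 1L, n)
  scale_j <- matrix(stats::runif(3L * n, 0.9, 1.1), n, 3L)
  suv_j <- matrix(stats::runif(4L * n, 0.9, 1.1), n, 4L)
  bladder_j <- stats::runif(n, 2 / 3, 4 / 3)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    suv <- base$organ_suv
    suv[c("soft", "lung", "liver", "brain")] <-
      suv[c("soft", "lung", "liver", "brain")] * suv_j[i, ]
    suv["bladder"] <- suv["bladder"] * bladder_j[i]
    cfg <- phantom_config(
      grid_shape = base$grid_shape, spacing = base$spacing, sex = base$sex,
      torso_height_scale = base$torso_height_scale * scale_j[i, 1],
      torso_width_scale = base$torso_width_scale * scale_j[i, 2],
      torso_depth_scale = base$torso_depth_scale * scale_j[i, 3],
      organ_suv = suv, noise_sd = base$noise_sd, lesions = base$lesions,
      head_y_offset = base$head_y_offset, arms = base$arms,
      seed = subj_seed[i])
    out[[i]] <- generate_phantom(cfg)
  }
  out
}
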