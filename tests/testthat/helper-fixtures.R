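# Shared fixtures, computed once per test run.

tp_cfg <- pet_config()

# default noiseless male phantom and the standard body anchored on it
tp_phantom0 <- generate_phantom(phantom_config(noise_sd = 0))
tp_std <- standard_body(tp_phantom0$volume, tp_cfg)

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# 26-neighborhood morphology on logical arrays
dilate1 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- array(FALSE, d)
    xs <- seq_len(d[1] - abs(dx)); ys <- seq_len(d[2] - abs(dy))
    zs <- seq_len(d[3] - abs(dz))
    sh[xs + max(dx, 0), ys + max(dy, 0), zs + max(dz, 0)] <-
      m[xs - min(dx, 0), ys - min(dy, 0), zs - min(dz, 0)]
    out <- out | sh
  }
  out
}
erode1 <- function(m) !dilate1(!m)

sphere_mask <- function(d, center, radius) {
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  outer(outer((x - center[1])^2, (y - center[2])^2, "+"),
        (z - center[3])^2, "+") <= radius^2
}

plane_vec <- function(x) unlist(x[c("ns_z", "th_z", "bl_z", "lv_z",
                                    "ac_left_x", "ac_right_x",
                                    "a_y", "p_y")])
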