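# shared fixtures: all built in code, nothing loaded from disk

.pw_cache <- new.env(parent = emptyenv())

# default noiseless Bragg model (built once per test run; construction is
# the expensive step)
test_bragg_model <- function() {
  if (is.null(.pw_cache$model)) {
    .pw_cache$model <- bragg_model(bragg_params(noise_cv = 0))
  }
  .pw_cache$model
}

# plateau 1.0 up to 100 mm, linear fall to 0 at 110 mm, sampled every 2 mm
ramp_curve <- function() {
  d <- seq(2, 120, by = 2)
  s <- ifelse(d <= 100, 1, pmax(0, (110 - d) / 10))
  depth_dose_curve(d, s)
}

# curve with a plateau at 1.0 then a linear falloff from depth `a` (signal
# 1) to `a + fall_len` (signal 0); with a pitch fine enough that the
# plateau/falloff kink and each crossing lie in different segments, the
# crossings of fraction f sit exactly at a + (1 - f) * fall_len
linear_falloff_curve <- function(a, fall_len, pitch = 0.2, z_max = 300) {
  d <- seq(pitch / 2, z_max, by = pitch)
  s <- pmin(1, pmax(0, (a + fall_len - d) / fall_len))
  depth_dose_curve(d, s)
}

# brute-force exact two-sided Wilcoxon p by enumerating all 2^n sign
# assignments (the independent oracle for the DP implementation)
bf_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  wp <- vapply(0:(2^n - 1), function(b) {
    sum(r[bitwAnd(bitwShiftR(b, 0:(n - 1)), 1L) == 1L])
  }, 0)
  p_le <- mean(wp <= w_plus + 1e-9)
  p_ge <- mean(wp >= w_plus - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force WEPL by fixed-step midpoint sampling along a ray
bf_step_wepl <- function(grid, origin, direction, length_mm, step = 0.01) {
  t <- seq(step / 2, length_mm, by = step)
  pts <- cbind(origin[1] + t * direction[1],
               origin[2] + t * direction[2],
               origin[3] + t * direction[3])
  d <- dim(grid$values)
  idx <- floor(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  sum(grid$values[idx[ok, , drop = FALSE]]) * step
}

# small uniform water-equivalent grid (kind rsp)
water_grid <- function(dims = c(30, 20, 10), spacing = c(2, 2, 2),
                       origin = c(0, 0, 0), rsp = 1) {
  vox_grid(array(rsp, dims), spacing, origin, kind = "rsp")
}

# 1-mm slab geometry used for pullback-style dose tests: 300 x 5 x 5 water
# grid with a 30-mm slab of the given rsp at x in [10, 40) mm
slab_phantom <- function(slab_rsp = 0.080) {
  arr <- array(1, c(300, 5, 5))
  arr[11:40, , ] <- slab_rsp
  rsp <- vox_grid(arr, c(1, 1, 1), kind = "rsp")
  mask <- vox_grid(array(rep(c(FALSE, TRUE, FALSE), c(10, 30, 260)),
                         c(300, 5, 5)), c(1, 1, 1), kind = "mask")
  list(rsp = rsp, mask = mask)
}

# head-and-neck-like phantom with proximal/distal OARs for the posterior
# beam (cached: dose-engine tests reuse it)
test_patient <- function() {
  if (is.null(.pw_cache$patient)) {
    cs <- do.call(case_spec,
                  c(list(name = "hn_test"), default_study_config()$case_defaults))
    .pw_cache$patient <- generate_patient_phantom(cs, default_calibration())
  }
  .pw_cache$patient
}
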