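test_that("water identity: WEPL through unit-RSP material equals geometric length", {
  g <- water_grid(dims = c(40, 10, 10), spacing = c(2, 2, 2))
  # 50-mm in-grid segment along x
  r <- ray3(c(5, 10, 10), c(1, 0, 0), 50)
  expect_equal(ray_trace_wet(g, r), 50)
  # oblique unit-RSP path: WEPL equals the in-grid chord length
  r2 <- ray3(c(-10, -10, 2), c(1, 1, 0) / sqrt(2))
  chord <- ray_trace_wet(g, r2)
  expect_equal(chord, sqrt(2) * 20, tolerance = 1e-9)
})

test_that("a low-RSP slab in vacuum contributes thickness times RSP", {
  arr <- array(0, c(60, 5, 5))
  arr[16:45, , ] <- 0.2   # 30-mm slab at 1-mm voxels
  g <- vox_grid(arr, c(1, 1, 1), kind = "rsp")
  expect_equal(ray_trace_wet(g, ray3(c(-5, 2.5, 2.5), c(1, 0, 0))), 6.0)
})

test_that("WEPL is additive over sub-segments", {
  set.seed(4)
  g <- vox_grid(array(runif(30 * 12 * 8, 0.2, 1.8), c(30, 12, 8)),
                c(1.5, 2, 2.5), origin = c(-3, 1, -7), kind = "rsp")
  o <- c(-20, -5, -15)
  d <- c(2, 1.2, 1.1); d <- d / sqrt(sum(d^2))
  whole <- suppressWarnings(ray_trace_wet(g, ray3(o, d, 80)))
  part1 <- suppressWarnings(ray_trace_wet(g, ray3(o, d, 33.7)))
  part2 <- suppressWarnings(ray_trace_wet(g, ray3(o + 33.7 * d, d, 80 - 33.7)))
  expect_equal(whole, part1 + part2, tolerance = 1e-9)
})

test_that("Siddon traversal matches 0.01-mm step integration on oblique rays", {
  pp <- test_patient()
  g <- phantom_rsp(pp$phantom, default_calibration())
  set.seed(21)
  for (i in 1:20) {
    ang <- runif(1, 0, 2 * pi)
    o <- c(200 * cos(ang), 200 * sin(ang), runif(1, -40, 40))
    tgt <- c(runif(2, -15, 15), runif(1, -10, 10))
    dirn <- tgt - o; dirn <- dirn / sqrt(sum(dirn^2))
    w <- suppressWarnings(ray_trace_wet(g, ray3(o, dirn, 500)))
    wb <- bf_step_wepl(g, o, dirn, 500)
    expect_lt(abs(w - wb) / wb, 1e-4)
  }
})

test_that("a ray missing the grid returns zero WEPL with a warning", {
  g <- water_grid()
  expect_warning(w <- ray_trace_wet(g, ray3(c(-100, -100, -100), c(0, 0, 1))),
                 class = "protonWET_ray_miss_warning")
  expect_equal(w, 0)
})

test_that("device thickness is the in-mask intersection length", {
  arr <- array(FALSE, c(60, 80, 10))
  arr[16:45, , ] <- TRUE   # 30-mm slab along x, laterally wide
  m <- vox_grid(arr, c(1, 1, 1), kind = "mask")
  expect_equal(device_thickness(m, ray3(c(-5, 10, 5), c(1, 0, 0))), 30)
  # 45-degree ray crosses the 30-mm slab over a sqrt(2)-longer path
  expect_equal(device_thickness(m, ray3(c(10, 0, 5), c(1, 1, 0) / sqrt(2))),
               30 * sqrt(2), tolerance = 1e-9)
  expect_warning(t0 <- device_thickness(m, ray3(c(-5, 10, 50), c(1, 0, 0))),
                 class = "protonWET_ray_miss_warning")
  expect_equal(t0, 0)
})

test_that("TPS SPR of a homogeneous slab equals its calibration RSP", {
  cal <- default_calibration()
  spec <- device_spec("cushion", true_rsp = 0.101, thickness_mm = 30,
                      tps_rsp = 0.080)
  dev <- generate_device_phantom(spec, cal)
  ray <- ray3(c(30, dev$phantom$origin[2] - 1, 5), c(0, 1, 0))
  m1 <- tps_spr_at_location(dev$phantom, dev$mask, ray, cal, n_repeats = 1)
  m3 <- tps_spr_at_location(dev$phantom, dev$mask, ray, cal, n_repeats = 3)
  expect_equal(m1$spr, 0.080, tolerance = 1e-9)
  expect_equal(m3$spr, m1$spr)          # deterministic repeats are identical
  expect_equal(m1$thickness_mm, 30)
})

test_that("SPR comparison reproduces the benchmark arithmetic", {
  mk <- function(spr, thick, name) {
    device_spr(list(spr_at_location(spr * thick, thick)), name)
  }
  same <- compare_spr(mk(0.070, 50, "bag"), mk(0.070, 50, "bag"))
  expect_equal(same$percent_diff, 0)
  cushion <- compare_spr(mk(0.080, 30, "cushion"), mk(0.101, 30, "cushion"))
  expect_equal(round(cushion$percent_diff, 1), -20.8)
  bos <- compare_spr(mk(0.122, 32.8, "bos"), mk(0.189, 32.8, "bos"))
  expect_equal(round(bos$wet_diff_mm, 2), -2.20)
  expect_error(compare_spr(mk(0.08, 30, "a"), mk(0.1, 30, "b")),
               class = "protonWET_error")
})
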