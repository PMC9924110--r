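test_that("depth_dose_curve validates its invariants", {
  expect_error(depth_dose_curve(1:5, rep(1, 5)), class = "protonWET_error")
  expect_error(depth_dose_curve(c(1:9, 9), rep(1, 10)),
               class = "protonWET_monotonicity_error")
  expect_error(depth_dose_curve(1:10, rep(0, 10)), class = "protonWET_error")
  expect_error(depth_dose_curve(1:10, c(rep(1, 9), -0.1)),
               class = "protonWET_error")
})

test_that("distal threshold depth interpolates the 2-mm ramp exactly", {
  crv <- ramp_curve()
  expect_equal(distal_threshold_depth(crv, 0.8), 102.0)
  expect_equal(distal_threshold_depth(crv, 0.9), 101.0)
  rm <- range_metrics(crv)
  expect_equal(rm$r80_mm, 102.0)
  expect_equal(rm$r90_mm, 101.0)
  expect_lte(rm$r90_mm, rm$r80_mm)
})

test_that("shifting a curve shallower shifts both range metrics by the same amount", {
  crv <- ramp_curve()
  shifted <- depth_dose_curve(crv$depths_mm,
                              approx(crv$depths_mm - 5, crv$signal,
                                     xout = crv$depths_mm, rule = 2)$y)
  rm0 <- range_metrics(crv)
  rm1 <- range_metrics(shifted)
  expect_equal(rm0$r80_mm - rm1$r80_mm, 5, tolerance = 0.05)
  expect_equal(rm0$r90_mm - rm1$r90_mm, 5, tolerance = 0.05)
})

test_that("curves without a resolvable distal edge raise range-not-found", {
  flat <- depth_dose_curve(1:20, rep(1, 20))
  expect_error(distal_threshold_depth(flat, 0.8),
               class = "protonWET_range_not_found_error")
  # truncated: maximum at the last sample
  rising <- depth_dose_curve(1:20, seq(0.1, 2, length.out = 20))
  expect_error(range_metrics(rising), class = "protonWET_range_not_found_error")
})

test_that("the most distal crossing wins: a spurious shallow dip changes nothing", {
  crv <- ramp_curve()
  dipped <- crv$signal
  dipped[10] <- 0.5   # noise dip in the plateau at 20 mm
  crv2 <- depth_dose_curve(crv$depths_mm, dipped)
  expect_equal(distal_threshold_depth(crv2, 0.8),
               distal_threshold_depth(crv, 0.8))
  expect_equal(distal_threshold_depth(crv2, 0.9),
               distal_threshold_depth(crv, 0.9))
})

test_that("WET is the mean R80/R90 shift between reference and sample", {
  # linear falloffs interpolate exactly: crossings at a + (1 - f) * L
  ref <- linear_falloff_curve(a = 257.2, fall_len = 14)   # r80 260.0, r90 258.6
  sam <- linear_falloff_curve(a = 254.7, fall_len = 16)   # r80 257.9, r90 256.3
  expect_equal(distal_threshold_depth(ref, 0.8), 260.0)
  expect_equal(distal_threshold_depth(ref, 0.9), 258.6)
  expect_equal(distal_threshold_depth(sam, 0.8), 257.9)
  expect_equal(distal_threshold_depth(sam, 0.9), 256.3)
  expect_equal(wet_from_curves(ref, sam), 2.2)
  expect_equal(wet_from_curves(ref, ref), 0.0)
  expect_warning(wet_from_curves(sam, ref),
                 class = "protonWET_negative_wet_warning")
})

test_that("noiseless WET recovery is within 0.1 mm for representative thicknesses", {
  m <- test_bragg_model()
  ref <- generate_idd(m, 0)
  for (w in c(0.5, 5, 30)) {
    expect_lt(abs(wet_from_curves(ref, generate_idd(m, w)) - w), 0.1)
  }
})

test_that("per-location SPR is WET over thickness, with degenerate input rejected", {
  meas <- spr_at_location(10.1, 100)
  expect_equal(meas$spr, 0.101)
  expect_equal(spr_at_location(25, 25)$spr, 1.0)
  expect_error(spr_at_location(10, 0), class = "protonWET_error")
})

test_that("device SPR aggregates location measurements", {
  ms <- lapply(c(0.101, 0.095, 0.107),
               function(s) spr_at_location(s * 30, 30))
  res <- device_spr(ms, "cushion")
  expect_equal(res$mean_spr, 0.101)
  expect_equal(res$spr_sd, sd(c(0.101, 0.095, 0.107)))
  single <- device_spr(ms[1], "cushion")
  expect_equal(single$mean_spr, 0.101)
  expect_true(is.na(single$spr_sd))
  expect_error(device_spr(list()), class = "protonWET_error")
})
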