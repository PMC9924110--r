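test_that("override records are ratio corrections", {
  ov <- make_override(0.080, 0.101)
  expect_equal(ov$factor, 1.2625)
  expect_equal(make_override(0.07, 0.07)$factor, 1)
  expect_error(make_override(0, 0.1), class = "protonWET_error")
})

test_that("apply_override rescales inside the mask only, exactly", {
  sl <- slab_phantom(0.080)
  ov <- make_override(0.080, 0.101)
  out <- apply_override(sl$rsp, sl$mask, ov)
  expect_equal(out$values[20, 3, 3], 0.101)
  expect_equal(out$values[100, 3, 3], 1)           # outside mask unchanged
  ident <- apply_override(sl$rsp, sl$mask, make_override(0.08, 0.08))
  expect_identical(ident$values, sl$rsp$values)
  empty <- vox_grid(array(FALSE, dim(sl$rsp$values)), c(1, 1, 1), kind = "mask")
  expect_warning(noop <- apply_override(sl$rsp, empty, ov),
                 class = "protonWET_empty_mask_warning")
  expect_identical(noop$values, sl$rsp$values)
})

test_that("after the override the TPS re-measures exactly the measured SPR", {
  cal <- default_calibration()
  spec <- device_spec("cushion", true_rsp = 0.101, thickness_mm = 30,
                      tps_rsp = 0.080)
  dev <- generate_device_phantom(spec, cal)
  rsp <- phantom_rsp(dev$phantom, cal)
  rsp2 <- apply_override(rsp, dev$mask, make_override(0.080, 0.101))
  ray <- ray3(c(30, rsp2$origin[2] - 1, 5), c(0, 1, 0))
  m <- tps_spr_at_location(rsp2, dev$mask, ray, n_repeats = 1)
  expect_equal(m$spr, 0.101, tolerance = 1e-12)
})

test_that("SOBP depth dose has an exact plateau and an 80/20-calibrated falloff", {
  f <- 4
  expect_equal(sobp_depth_dose(125, 150, 50, f), 1)     # plateau centre
  expect_equal(sobp_depth_dose(150, 150, 50, f), 1)     # distal plateau edge
  expect_equal(sobp_depth_dose(150 + 10 * f, 150, 50, f), 0)
  # closed-form check of the raised-cosine: 80% and 20% points f mm apart
  L <- f / ((acos(-0.6) - acos(0.6)) / pi)
  w80 <- 150 + L * acos(0.6) / pi
  w20 <- 150 + L * acos(-0.6) / pi
  expect_equal(sobp_depth_dose(w80, 150, 50, f), 0.8)
  expect_equal(sobp_depth_dose(w20, 150, 50, f), 0.2)
  expect_equal(w20 - w80, f)
  expect_error(sobp_depth_dose(1, 150, 50, 0), class = "protonWET_error")
})

test_that("homogeneous water: plateau voxels receive the prescription", {
  g <- water_grid(dims = c(100, 11, 11), spacing = c(2, 2, 2))
  beam <- beam_spec(270, isocenter_mm = c(100, 11, 11),
                    sobp_range_mm = 150, sobp_modulation_mm = 60)
  d <- compute_dose(g, list(beam), prescription_dose = 100)
  # voxel at x = 121 mm: WEPL 121, inside plateau [90, 150]
  expect_equal(d$values[61, 6, 6], 100)
  expect_true(all(d$values >= 0 & d$values <= 100 + 1e-9))
})

test_that("two equal-weight opposed beams sum to the prescription in the joint plateau", {
  g <- water_grid(dims = c(100, 11, 11), spacing = c(2, 2, 2))
  b1 <- beam_spec(270, c(100, 11, 11), sobp_range_mm = 150,
                  sobp_modulation_mm = 100, weight = 0.5)
  b2 <- beam_spec(90, c(100, 11, 11), sobp_range_mm = 150,
                  sobp_modulation_mm = 100, weight = 0.5)
  plan <- plan_spec(list(b1, b2), prescription_dose = 100)
  d <- compute_dose(g, plan)
  # centre voxel: WEPL 100 from either side, in both plateaus [50, 150]
  expect_equal(d$values[50, 6, 6], 100)
})

test_that("marching WEPL agrees with the exact cumulative sum for axis-aligned beams", {
  set.seed(12)
  g <- vox_grid(array(runif(25 * 18 * 9, 0.2, 1.5), c(25, 18, 9)),
                c(1.5, 2, 2.5), origin = c(-10, 0, -5), kind = "rsp")
  for (dirn in list(c(0, 1, 0), c(-1, 0, 0))) {
    exact <- protonWET:::wepl_grid_axis(g, which(dirn != 0), sum(dirn) > 0)
    marched <- protonWET:::wepl_grid_march(g, dirn, step = 0.05)
    expect_lt(max(abs(exact - marched)), 0.1)
  }
})

test_that("overriding an upstream slab pulls the distal edge back by thickness times delta-RSP", {
  sl <- slab_phantom(0.080)
  beam <- beam_spec(270, isocenter_mm = c(150, 2.5, 2.5),
                    sobp_range_mm = 150, sobp_modulation_mm = 50)
  d0 <- compute_dose(sl$rsp, list(beam))
  ov <- list(list(record = make_override(0.080, 0.101), mask = sl$mask))
  d1 <- compute_dose(sl$rsp, list(beam), overrides = ov)
  prof0 <- depth_dose_curve(seq(0.5, 299.5, 1), d0$values[, 3, 3])
  prof1 <- depth_dose_curve(seq(0.5, 299.5, 1), d1$values[, 3, 3])
  pullback <- distal_threshold_depth(prof0, 0.8) - distal_threshold_depth(prof1, 0.8)
  expect_equal(pullback, 30 * (0.101 - 0.080), tolerance = 0.2 / 0.63)
  expect_gt(pullback, 0)
})

test_that("scenario set is nominal plus 6 cardinal shifts times 2 range scales", {
  sc <- scenario_set(3, 0.035)
  expect_equal(nrow(sc), 13)
  expect_equal(sc$name[1], "nominal")
  expect_equal(sum(sc$rsp_scale == 1 - 0.035), 6)
  expect_equal(sum(sc$rsp_scale == 1 + 0.035), 6)
  shifts <- unique(sc[-1, c("dx", "dy", "dz")])
  expect_equal(nrow(shifts), 6)
  expect_true(all(abs(as.matrix(shifts)) %in% c(0, 3)))
})

test_that("zero uncertainty makes all 13 scenario doses identical; range scaling moves the distal edge", {
  sl <- slab_phantom(0.5)
  beam1 <- beam_spec(270, c(150, 2.5, 2.5), sobp_range_mm = 150,
                     sobp_modulation_mm = 50, weight = 0.5)
  beam2 <- beam_spec(90, c(150, 2.5, 2.5), sobp_range_mm = 150,
                     sobp_modulation_mm = 50, weight = 0.5)
  plan0 <- plan_spec(list(beam1, beam2), setup_uncertainty_mm = 0,
                     range_uncertainty_fraction = 0)
  sc0 <- scenario_doses(sl$rsp, plan0)
  expect_length(sc0, 13)
  for (i in 2:13) expect_identical(sc0[[i]]$values, sc0[[1]]$values)

  plan <- plan_spec(list(beam1, beam2), setup_uncertainty_mm = 3,
                    range_uncertainty_fraction = 0.035)
  sc <- scenario_doses(sl$rsp, plan)
  # underdense scenario (rsp scale < 1): the distal edge moves deeper
  prof_nom <- depth_dose_curve(seq(0.5, 299.5, 1), sc$nominal$values[, 3, 3])
  low_names <- grep("scale0.965", names(sc), fixed = TRUE)
  prof_low <- depth_dose_curve(seq(0.5, 299.5, 1), sc[[low_names[1]]]$values[, 3, 3])
  expect_gt(distal_threshold_depth(prof_low, 0.8),
            distal_threshold_depth(prof_nom, 0.8))
})

test_that("dose computation is deterministic", {
  pp <- test_patient()
  cal <- default_calibration()
  d1 <- compute_dose(pp$phantom, pp$plan, cal)
  d2 <- compute_dose(pp$phantom, pp$plan, cal)
  expect_identical(d1$values, d2$values)
})
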