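cal <- default_calibration()

test_that("device phantom voxelizes the slab and records exact ground truth", {
  spec <- device_spec("cushion", true_rsp = 0.101, thickness_mm = 30,
                      tps_rsp = 0.080, n_locations = 3)
  dev <- generate_device_phantom(spec, cal, spacing_mm = 1)
  # 30-mm slab on a 1-mm grid: mask columns are 30 voxels deep
  col <- dev$mask$values[10, , 3]
  expect_equal(sum(col), 30)
  expect_equal(hu_to_rsp(dev$truth$reported_hu[1], cal), 0.080,
               tolerance = 1e-7)
  expect_equal(round(dev$truth$injected_pct, 1), rep(-20.8, 3))
})

test_that("zero jitter makes all ground-truth location SPRs identical", {
  spec <- device_spec("d", true_rsp = 0.15, thickness_mm = 20, tps_rsp = 0.12,
                      n_locations = 3, location_jitter_cv = 0)
  dev <- generate_device_phantom(spec, cal)
  expect_equal(dev$truth$true_rsp, rep(0.15, 3))
  jspec <- device_spec("d", true_rsp = 0.15, thickness_mm = 20, tps_rsp = 0.12,
                       n_locations = 3, location_jitter_cv = 0.05)
  jdev1 <- generate_device_phantom(jspec, cal, seed = 9)
  jdev2 <- generate_device_phantom(jspec, cal, seed = 9)
  expect_identical(jdev1$truth$true_rsp, jdev2$truth$true_rsp)
  expect_gt(sd(jdev1$truth$true_rsp), 0)
})

test_that("slabs thinner than 4 voxels are rejected as unresolved", {
  spec <- device_spec("thin", true_rsp = 0.2, thickness_mm = 3, tps_rsp = 0.15)
  expect_error(generate_device_phantom(spec, cal, spacing_mm = 1),
               class = "protonWET_resolution_error")
})

test_that("measured SPR on a synthetic slab recovers the injected truth", {
  m <- test_bragg_model()
  spec <- device_spec("bos_body", true_rsp = 0.189, thickness_mm = 33,
                      tps_rsp = 0.122, n_locations = 3)
  dev <- generate_device_phantom(spec, cal)
  res <- simulate_device_measurement(dev, m)
  expect_equal(res$mean_spr, 0.189, tolerance = 0.002 / 0.189)
})

test_that("patient phantom: equal beam weights and SOBP ranges cover the CTV", {
  pp <- test_patient()
  w <- vapply(pp$plan$beams, `[[`, 0, "weight")
  expect_equal(w, c(0.5, 0.5))
  rsp <- phantom_rsp(pp$phantom, cal)
  # ray-trace oracle: each beam's range must reach the CTV distal edge
  for (b in pp$plan$beams) {
    th <- b$gantry_angle_deg * pi / 180
    d <- c(-sin(th), -cos(th), 0)
    far <- pp$case$ctv_center_mm - 400 * d
    wepl_distal <- suppressWarnings(
      ray_trace_wet(rsp, ray3(far, d, 400 + pp$case$ctv_radius_mm)))
    expect_gte(b$sobp_range_mm, wepl_distal)
  }
})

test_that("without a device the phantom is independent of the device calibration", {
  base <- default_study_config()$case_defaults
  base$device_thickness_mm <- 0
  csa <- do.call(case_spec, c(list(name = "nodev_a"), base))
  base$device_tps_rsp <- 0.3
  csb <- do.call(case_spec, c(list(name = "nodev_b"), base))
  pa <- generate_patient_phantom(csa, cal)
  pb <- generate_patient_phantom(csb, cal)
  expect_identical(pa$phantom$values, pb$phantom$values)
  expect_equal(sum(pa$masks$device$values), 0)
  for (i in 1:2) {
    expect_equal(pa$plan$beams[[i]]$sobp_range_mm,
                 pb$plan$beams[[i]]$sobp_range_mm)
  }
})

test_that("geometrically impossible cases are rejected", {
  expect_error(case_spec(body_radius_mm = 20, ctv_radius_mm = 25),
               class = "protonWET_geometry_error")
  expect_error(case_spec(gantry_angles_deg = 180), class = "protonWET_error")
  bad_oar <- list(list(name = "out", center_mm = c(500, 0, 0), radius_mm = 5))
  cs <- do.call(case_spec, c(list(oars = bad_oar),
                             default_study_config()$case_defaults["body_radius_mm"]))
  expect_error(generate_patient_phantom(cs, cal),
               class = "protonWET_geometry_error")
})
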