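#' Specification of a synthetic immobilization device
#'
#' Describes a homogeneous slab device with known ground truth: its true
#' relative stopping power, physical thickness, and the CT number a virtual
#' scanner assigns to its voxels.  The mismatch between `true_rsp` and the
#' calibration-curve RSP of `reported_hu` is the injected planning-system
#' error this package is designed to quantify.  Either `reported_hu` or a
#' target `tps_rsp` (converted through the calibration curve by the
#' phantom generator) must be given.
#'
#' @param name device name.
#' @param true_rsp ground-truth relative stopping power (> 0).
#' @param thickness_mm physical slab thickness (mm, > 0).
#' @param reported_hu HU assigned to device voxels by the virtual scanner.
#' @param tps_rsp alternatively, the RSP the planning system should derive;
#'   the generator picks `reported_hu` so the calibration yields this value.
#' @param n_locations number of BB-marked sample locations (>= 1).
#' @param location_jitter_cv relative spread of the per-location true RSP
#'   (multiplicative Gaussian; 0 = identical locations).
#' @return An object of class `device_spec`.
#' @export
device_spec <- function(name, true_rsp, thickness_mm, reported_hu = NULL,
                        tps_rsp = NULL, n_locations = 3L,
                        location_jitter_cv = 0) {
  pw_check(true_rsp > 0, "`true_rsp` must be positive")
  pw_check(thickness_mm > 0, "`thickness_mm` must be positive")
  pw_check(n_locations >= 1, "`n_locations` must be at least 1")
  pw_check(location_jitter_cv >= 0, "`location_jitter_cv` must be non-negative")
  pw_check(!is.null(reported_hu) || !is.null(tps_rsp),
           "give either `reported_hu` or `tps_rsp`")
  structure(list(name = name, true_rsp = true_rsp,
                 thickness_mm = thickness_mm,
                 reported_hu = reported_hu, tps_rsp = tps_rsp,
                 n_locations = as.integer(n_locations),
                 location_jitter_cv = location_jitter_cv),
            class = "device_spec")
}

#' Generate a CT phantom of a slab device with known injected SPR error
#'
#' Builds an air-background voxel phantom containing a homogeneous slab of
#' the device's reported HU, a device contour mask, and a ground-truth
#' record: per BB-marked location, the true RSP (with optional jitter), the
#' physical thickness, the calibration-derived TPS RSP, and the injected
#' percent error `100 * (tps_rsp - true_rsp) / true_rsp`, so downstream
#' estimates can be compared to truth without re-deriving it.
#'
#' The slab's thickness axis is y; BB locations are spread along x on the
#' slab surface at the central z slice.
#'
#' @param spec a [device_spec()].
#' @param curve a [calibration_curve()] used by the virtual scanner.
#' @param spacing_mm isotropic voxel size (mm); the slab must be at least
#'   4 voxels thick.
#' @param lateral_mm slab extent along x and z (mm).
#' @param air_margin_mm air padding on each side of the slab along y (mm).
#' @param seed RNG seed for the per-location RSP jitter.
#' @return A list of class `device_phantom` with elements `phantom`
#'   (`vox_grid` of HU), `mask`, `truth` (data frame), and `spec`.
#' @export
generate_device_phantom <- function(spec, curve, spacing_mm = 1,
                                    lateral_mm = 60, air_margin_mm = 20,
                                    seed = 1L) {
  pw_check(inherits(spec, "device_spec"), "`spec` must be a device_spec")
  n_thick <- round(spec$thickness_mm / spacing_mm)
  if (n_thick < 4 || abs(n_thick * spacing_mm - spec$thickness_mm) > 1e-9) {
    pw_abort("grid must resolve the slab thickness with >= 4 whole voxels",
             "protonWET_resolution_error")
  }
  hu_dev <- if (!is.null(spec$reported_hu)) spec$reported_hu else
    rsp_to_hu(spec$tps_rsp, curve)
  pw_check(hu_dev >= min(curve$hu) && hu_dev <= max(curve$hu),
           "reported HU outside the calibration-curve domain")
  nx <- round(lateral_mm / spacing_mm)
  nz <- max(round(lateral_mm / 3 / spacing_mm), 5L)
  nm <- round(air_margin_mm / spacing_mm)
  ny <- n_thick + 2L * nm
  hu <- array(-1000, c(nx, ny, nz))
  jy <- (nm + 1L):(nm + n_thick)
  hu[, jy, ] <- hu_dev
  phantom <- vox_grid(hu, spacing = rep(spacing_mm, 3))
  mask_arr <- array(FALSE, c(nx, ny, nz))
  mask_arr[, jy, ] <- TRUE
  mask <- vox_grid(mask_arr, spacing = rep(spacing_mm, 3), kind = "mask")

  set.seed(seed)
  jit <- if (spec$location_jitter_cv > 0)
    1 + spec$location_jitter_cv * stats::rnorm(spec$n_locations) else
    rep(1, spec$n_locations)
  x_loc <- axis_centers(phantom, 1)[round(seq(0.2, 0.8, length.out = spec$n_locations) * nx)]
  z_loc <- rep(axis_centers(phantom, 3)[ceiling(nz / 2)], spec$n_locations)
  tps_rsp <- hu_to_rsp(hu_dev, curve)
  true_rsp <- spec$true_rsp * jit
  truth <- data.frame(
    location = seq_len(spec$n_locations),
    x_mm = x_loc, z_mm = z_loc,
    true_rsp = true_rsp,
    thickness_mm = n_thick * spacing_mm,
    reported_hu = hu_dev,
    tps_rsp = tps_rsp,
    injected_pct = 100 * (tps_rsp - true_rsp) / true_rsp
  )
  structure(list(phantom = phantom, mask = mask, truth = truth, spec = spec),
            class = "device_phantom")
}

# probe line through a BB location, perpendicular to the slab surface
device_probe_ray <- function(dev, location) {
  row <- dev$truth[dev$truth$location == location, ]
  ray3(c(row$x_mm, dev$phantom$origin[2] - 1, row$z_mm), c(0, 1, 0))
}

#' Simulate the range-shift (MLIC) measurement of a device phantom
#'
#' For each BB-marked location: acquire a reference IDD with the
#' unperturbed beam, a sample IDD with the device in the beam path (its
#' per-location true water-equivalent thickness `true_rsp * thickness`
#' shifts the curve shallower), estimate WET from the R80/R90 range shifts,
#' read the physical thickness off the CT contour along the perpendicular
#' probe line, and form SPR.  The device SPR averages the locations.
#'
#' @param dev a [generate_device_phantom()] result.
#' @param model a [bragg_model()] or [bragg_params()].
#' @param noise_cv per-chamber noise coefficient of variation (default 0:
#'   noiseless measurement).
#' @param seed base RNG seed for noisy acquisitions.
#' @return A [device_spr()] result.
#' @export
simulate_device_measurement <- function(dev, model, noise_cv = 0, seed = 1L) {
  pw_check(inherits(dev, "device_phantom"), "`dev` must be a device_phantom")
  if (!inherits(model, "bragg_model")) model <- bragg_model(model)
  meas <- vector("list", nrow(dev$truth))
  for (i in seq_len(nrow(dev$truth))) {
    row <- dev$truth[i, ]
    w_true <- row$true_rsp * row$thickness_mm
    ref <- generate_idd(model, 0, noise = noise_cv, seed = seed + 2L * i)
    sam <- generate_idd(model, w_true, noise = noise_cv, seed = seed + 2L * i + 1L)
    wet <- wet_from_curves(ref, sam)
    thick <- suppressWarnings(device_thickness(dev$mask, device_probe_ray(dev, row$location)))
    meas[[i]] <- spr_at_location(wet, thick, location_id = row$location)
  }
  device_spr(meas, device = dev$spec$name)
}

#' Planning-system SPR of a device phantom
#'
#' Runs the TPS-side measurement ([tps_spr_at_location()]) at every
#' BB-marked location of a generated device phantom, probing perpendicular
#' to the slab surface, and aggregates to a device SPR.
#'
#' @param dev a [generate_device_phantom()] result.
#' @param curve the clinical [calibration_curve()].
#' @param n_repeats repeated evaluations per location.
#' @return A [device_spr()] result.
#' @export
measure_device_tps <- function(dev, curve, n_repeats = 3L) {
  pw_check(inherits(dev, "device_phantom"), "`dev` must be a device_phantom")
  meas <- lapply(seq_len(nrow(dev$truth)), function(i) {
    tps_spr_at_location(dev$phantom, dev$mask, device_probe_ray(dev, i),
                        curve, n_repeats = n_repeats, location_id = i)
  })
  device_spr(meas, device = dev$spec$name)
}

#' Specification of a patient-like phantom and plan
#'
#' A cylindrical water-equivalent body (axis along z) with a spherical
#' clinical target volume (CTV), spherical organs at risk, and a cushion
#' slab under the body (posterior, at negative y).  The geometry emulates
#' a head-and-neck-like setup where posterior beams traverse the
#' immobilization device.
#'
#' @param name case identifier.
#' @param body_radius_mm radius of the body cylinder (mm).
#' @param ctv_center_mm,ctv_radius_mm CTV sphere (world mm; the body axis
#'   passes through x = 0, y = 0).
#' @param oars list of OARs, each `list(name=, center_mm=, radius_mm=)`.
#' @param device_thickness_mm,device_gap_mm cushion slab thickness and air
#'   gap between body surface and slab (mm); `device_thickness_mm = 0`
#'   omits the device.
#' @param device_tps_rsp RSP the planning system derives for the cushion
#'   (via the calibration curve); the measured/true RSP enters later
#'   through the density override.
#' @param gantry_angles_deg beam angles (2 to 4); 0 enters anterior (+y),
#'   180 posterior (through the cushion).
#' @param prescription_dose prescription in arbitrary dose units.
#' @param spacing_mm isotropic voxel size (mm).
#' @param z_extent_mm phantom length along the body axis (mm).
#' @param setup_uncertainty_mm,range_uncertainty_fraction robustness
#'   evaluation parameters.
#' @param wepl_margin_mm distal/proximal water-equivalent margin added
#'   around the CTV when setting each beam's SOBP range and modulation.
#' @param aperture_margin_mm lateral field margin beyond the CTV radius.
#' @return An object of class `case_spec`.
#' @export
case_spec <- function(name = "case",
                      body_radius_mm = 60,
                      ctv_center_mm = c(0, 0, 0),
                      ctv_radius_mm = 15,
                      oars = list(),
                      device_thickness_mm = 30,
                      device_gap_mm = 2,
                      device_tps_rsp = 0.080,
                      gantry_angles_deg = c(180, 90),
                      prescription_dose = 100,
                      spacing_mm = 2,
                      z_extent_mm = 40,
                      setup_uncertainty_mm = 3,
                      range_uncertainty_fraction = 0.035,
                      wepl_margin_mm = 5,
                      aperture_margin_mm = 6) {
  pw_check(body_radius_mm > 0, "`body_radius_mm` must be positive")
  pw_check(ctv_radius_mm > 0, "`ctv_radius_mm` must be positive")
  pw_check(sqrt(sum(ctv_center_mm[1:2]^2)) + ctv_radius_mm < body_radius_mm,
           "CTV must lie fully inside the body", "protonWET_geometry_error")
  pw_check(length(gantry_angles_deg) >= 2 && length(gantry_angles_deg) <= 4,
           "between 2 and 4 beams are required")
  pw_check(device_thickness_mm >= 0 && device_gap_mm >= 0,
           "device thickness and gap must be non-negative")
  structure(list(name = name, body_radius_mm = body_radius_mm,
                 ctv_center_mm = ctv_center_mm, ctv_radius_mm = ctv_radius_mm,
                 oars = oars,
                 device_thickness_mm = device_thickness_mm,
                 device_gap_mm = device_gap_mm,
                 device_tps_rsp = device_tps_rsp,
                 gantry_angles_deg = gantry_angles_deg,
                 prescription_dose = prescription_dose,
                 spacing_mm = spacing_mm, z_extent_mm = z_extent_mm,
                 setup_uncertainty_mm = setup_uncertainty_mm,
                 range_uncertainty_fraction = range_uncertainty_fraction,
                 wepl_margin_mm = wepl_margin_mm,
                 aperture_margin_mm = aperture_margin_mm),
            class = "case_spec")
}

sphere_mask <- function(template, center, radius) {
  x <- axis_centers(template, 1)
  y <- axis_centers(template, 2)
  z <- axis_centers(template, 3)
  d <- grid_dim(template)
  dx2 <- (x - center[1])^2
  dy2 <- (y - center[2])^2
  dz2 <- (z - center[3])^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
  vox_grid(array(arr, d), template$spacing, template$origin, kind = "mask")
}

# WEPL from outside the grid up to a world point, along unit direction d
wepl_to_point <- function(rsp_grid, point, d) {
  span <- sqrt(sum((grid_upper(rsp_grid) - rsp_grid$origin)^2)) + 10
  ray_trace_wet(rsp_grid, ray3(point - span * d, d, span))
}

gantry_direction <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(-sin(th), -cos(th), 0)   # 0 deg: source anterior (+y), beam travels -y
}

#' Generate a patient-like phantom with structures and an SOBP plan
#'
#' Builds the HU phantom (air background, water-equivalent body at HU 0,
#' cushion slab at the HU matching `device_tps_rsp`), the structure masks
#' (body, CTV, OARs, device), and a [plan_spec()] whose per-beam SOBP range
#' and modulation are set from ray-traced water-equivalent path lengths so
#' that the plateau covers the CTV with the configured margins.  Beam
#' ranges are derived from the planning-system view of the phantom (device
#' at its TPS RSP), as a clinical plan would be.
#'
#' @param case a [case_spec()].
#' @param curve a [calibration_curve()].
#' @return A list of class `patient_phantom` with `phantom`, `masks`
#'   (named list of `vox_grid` masks), `plan`, and `case`.
#' @export
generate_patient_phantom <- function(case, curve) {
  pw_check(inherits(case, "case_spec"), "`case` must be a case_spec")
  h <- case$spacing_mm
  pad <- 4 * h
  y_lo <- -case$body_radius_mm - case$device_gap_mm -
    case$device_thickness_mm - pad
  y_hi <- case$body_radius_mm + pad
  x_half <- case$body_radius_mm + pad
  nx <- ceiling(2 * x_half / h)
  ny <- ceiling((y_hi - y_lo) / h)
  nz <- ceiling(case$z_extent_mm / h)
  origin <- c(-nx * h / 2, y_lo, -nz * h / 2)
  hu <- array(-1000, c(nx, ny, nz))
  template <- vox_grid(hu, rep(h, 3), origin)
  x <- axis_centers(template, 1)
  y <- axis_centers(template, 2)
  in_body <- outer(x^2, y^2, `+`) <= case$body_radius_mm^2
  hu_dev <- rsp_to_hu(case$device_tps_rsp, curve)
  body_arr <- array(in_body, c(nx, ny, nz))
  hu[body_arr] <- 0
  dev_arr <- array(FALSE, c(nx, ny, nz))
  if (case$device_thickness_mm > 0) {
    y_top <- -case$body_radius_mm - case$device_gap_mm
    in_dev_y <- y >= y_top - case$device_thickness_mm & y < y_top
    dev_xy <- outer(abs(x) <= case$body_radius_mm, in_dev_y, `&`)
    dev_arr <- array(dev_xy, c(nx, ny, nz))
    pw_check(!any(dev_arr & body_arr), "device must be disjoint from the body",
             "protonWET_geometry_error")
    hu[dev_arr] <- hu_dev
  }
  phantom <- vox_grid(hu, rep(h, 3), origin)
  masks <- list(
    body = vox_grid(body_arr, rep(h, 3), origin, kind = "mask"),
    ctv = sphere_mask(template, case$ctv_center_mm, case$ctv_radius_mm),
    device = vox_grid(dev_arr, rep(h, 3), origin, kind = "mask")
  )
  for (o in case$oars) {
    m <- sphere_mask(template, o$center_mm, o$radius_mm)
    pw_check(sum(m$values) > 0, sprintf("OAR '%s' lies outside the grid", o$name),
             "protonWET_geometry_error")
    masks[[o$name]] <- m
  }
  pw_check(sum(masks$ctv$values) > 0, "CTV lies outside the grid",
           "protonWET_geometry_error")

  rsp <- phantom_rsp(phantom, curve)
  iso <- case$ctv_center_mm
  beams <- lapply(case$gantry_angles_deg, function(ang) {
    d <- gantry_direction(ang)
    w_distal <- wepl_to_point(rsp, iso + case$ctv_radius_mm * d, d)
    w_proximal <- wepl_to_point(rsp, iso - case$ctv_radius_mm * d, d)
    pw_check(w_distal > w_proximal,
             sprintf("beam at %g deg does not traverse the CTV", ang),
             "protonWET_geometry_error")
    beam_spec(gantry_angle_deg = ang, isocenter_mm = iso,
              sobp_range_mm = w_distal + case$wepl_margin_mm,
              sobp_modulation_mm = w_distal - w_proximal + 2 * case$wepl_margin_mm,
              weight = 1 / length(case$gantry_angles_deg),
              aperture_radius_mm = case$ctv_radius_mm + case$aperture_margin_mm)
  })
  plan <- plan_spec(beams, prescription_dose = case$prescription_dose,
                    setup_uncertainty_mm = case$setup_uncertainty_mm,
                    range_uncertainty_fraction = case$range_uncertainty_fraction)
  structure(list(phantom = phantom, masks = masks, plan = plan, case = case),
            class = "patient_phantom")
}
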