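#' Beam and plan specifications
#'
#' A beam is a broad (divergence-free) field in the axial plane with a
#' hard-edged circular aperture: gantry angle 0 deg enters from the
#' anterior (+y) side and travels towards -y; 180 deg enters posterior;
#' 90 deg travels towards +x.  The spread-out Bragg peak (SOBP) is
#' parameterised in water-equivalent depth by its distal range and
#' modulation (plateau width).
#'
#' @param gantry_angle_deg beam angle in the axial (x, y) plane.
#' @param isocenter_mm world point (mm) the aperture is centred on.
#' @param sobp_range_mm distal water-equivalent depth of the dose plateau
#'   (mm).
#' @param sobp_modulation_mm plateau water-equivalent width (mm),
#'   `0 < modulation <= range`.
#' @param weight fractional beam weight (> 0).
#' @param aperture_radius_mm hard field edge radius about the central axis
#'   (mm); `Inf` for a laterally unbounded beam.
#' @param distal_falloff_mm 80%-20% width of the distal dose falloff (mm).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(gantry_angle_deg, isocenter_mm = c(0, 0, 0),
                      sobp_range_mm, sobp_modulation_mm, weight = 1,
                      aperture_radius_mm = Inf, distal_falloff_mm = 4) {
  pw_check(sobp_range_mm > 0, "`sobp_range_mm` must be positive")
  pw_check(sobp_modulation_mm > 0 && sobp_modulation_mm <= sobp_range_mm,
           "modulation must lie in (0, range]")
  pw_check(weight > 0, "`weight` must be positive")
  pw_check(distal_falloff_mm > 0, "`distal_falloff_mm` must be positive")
  structure(list(gantry_angle_deg = gantry_angle_deg,
                 isocenter_mm = as.numeric(isocenter_mm),
                 sobp_range_mm = sobp_range_mm,
                 sobp_modulation_mm = sobp_modulation_mm,
                 weight = weight,
                 aperture_radius_mm = aperture_radius_mm,
                 distal_falloff_mm = distal_falloff_mm),
            class = "beam_spec")
}

#' @rdname beam_spec
#' @param beams list of `beam_spec` (2 to 4); weights must sum to 1.
#' @param prescription_dose prescription in arbitrary dose units.
#' @param setup_uncertainty_mm setup uncertainty for robustness scenarios
#'   (mm).
#' @param range_uncertainty_fraction relative range (stopping-power)
#'   uncertainty for robustness scenarios.
#' @export
plan_spec <- function(beams, prescription_dose = 100,
                      setup_uncertainty_mm = 3,
                      range_uncertainty_fraction = 0.035) {
  pw_check(length(beams) >= 2 && length(beams) <= 4,
           "a clinical plan has between 2 and 4 beams")
  pw_check(all(vapply(beams, inherits, TRUE, "beam_spec")),
           "all elements of `beams` must be beam_spec objects")
  w <- vapply(beams, `[[`, 0, "weight")
  pw_check(abs(sum(w) - 1) < 1e-9, "beam weights must sum to 1")
  pw_check(prescription_dose > 0, "`prescription_dose` must be positive")
  pw_check(setup_uncertainty_mm >= 0 && range_uncertainty_fraction >= 0,
           "uncertainties must be non-negative")
  structure(list(beams = beams, prescription_dose = prescription_dose,
                 setup_uncertainty_mm = setup_uncertainty_mm,
                 range_uncertainty_fraction = range_uncertainty_fraction),
            class = "plan_spec")
}

#' @export
print.plan_spec <- function(x, ...) {
  cat(sprintf("<plan_spec> %d beams, Rx %g; setup +/-%g mm, range +/-%g%%\n",
              length(x$beams), x$prescription_dose, x$setup_uncertainty_mm,
              100 * x$range_uncertainty_fraction))
  for (b in x$beams) {
    cat(sprintf("  gantry %6.1f deg: range %.1f mm, mod %.1f mm, weight %.2f\n",
                b$gantry_angle_deg, b$sobp_range_mm, b$sobp_modulation_mm,
                b$weight))
  }
  invisible(x)
}

#' Density override record
#'
#' The correction applied to a device after its SPR has been measured: the
#' stopping power inside the device contour is multiplied by
#' `factor = measured_spr / tps_spr`, so a subsequent planning-system SPR
#' measurement through the contour returns the measured value exactly.
#' (SPR is approximately proportional to mass density for a fixed
#' material, so a ratio in stopping-power space is equivalent to the
#' clinical density override.)
#'
#' @param tps planning-system [device_spr()] result, or a positive scalar.
#' @param measured measured [device_spr()] result, or a positive scalar.
#' @param device device name (taken from the results when available).
#' @return An object of class `override_record` with `tps_spr`,
#'   `measured_spr`, and `factor`.
#' @export
make_override <- function(tps, measured, device = NULL) {
  get_spr <- function(x) if (inherits(x, "device_spr_result")) x$mean_spr else as.numeric(x)
  t <- get_spr(tps); m <- get_spr(measured)
  pw_check(is.finite(t) && t > 0, "TPS SPR must be positive")
  pw_check(is.finite(m) && m > 0, "measured SPR must be positive")
  if (is.null(device)) {
    device <- if (inherits(tps, "device_spr_result")) tps$device else "device"
  }
  structure(list(device = device, tps_spr = t, measured_spr = m,
                 factor = m / t),
            class = "override_record")
}

#' Apply a density override to a stopping-power grid
#'
#' Multiplies the relative stopping power inside the mask by the override
#' factor; voxels outside the mask are unchanged.
#'
#' @param rsp_grid a `vox_grid` of kind `"rsp"`.
#' @param mask device contour (`vox_grid` mask, same geometry).
#' @param record an [make_override()] record.
#' @return The modified rsp `vox_grid`.
#' @export
apply_override <- function(rsp_grid, mask, record) {
  pw_check(inherits(rsp_grid, "vox_grid") && rsp_grid$kind == "rsp",
           "`rsp_grid` must be a vox_grid of kind 'rsp'")
  pw_check(inherits(record, "override_record"), "`record` must be an override_record")
  check_same_grid(rsp_grid, mask)
  if (!any(mask$values)) {
    pw_warn("override mask is empty; nothing changed",
            "protonWET_empty_mask_warning")
    return(rsp_grid)
  }
  rsp_grid$values[mask$values] <- rsp_grid$values[mask$values] * record$factor
  rsp_grid
}

# 80-20 width of a half-cosine ramp as a fraction of its full width
COS_RAMP_8020 <- (acos(-0.6) - acos(0.6)) / pi

#' Longitudinal SOBP dose as a function of water-equivalent depth
#'
#' The spread-out Bragg peak is modelled as a plateau of relative dose 1.0
#' on `[range - modulation, range]`, a raised-cosine distal falloff whose
#' 80%-20% width equals `distal_falloff_mm`, and a raised-cosine proximal
#' ramp of the same shape below the plateau.  The dose reaches 0 at
#' `range + 2.44 * distal_falloff_mm` (within the `range + 3 * falloff`
#' support bound) and is continuously differentiable everywhere.
#'
#' @param wepl_mm water-equivalent depth(s), vectorized.
#' @param range_mm distal edge of the plateau (mm WEPL).
#' @param modulation_mm plateau width (mm WEPL).
#' @param distal_falloff_mm 80%-20% falloff width (mm, > 0).
#' @return Relative dose in `[0, 1]`.
#' @export
sobp_depth_dose <- function(wepl_mm, range_mm, modulation_mm,
                            distal_falloff_mm = 4) {
  pw_check(distal_falloff_mm > 0, "`distal_falloff_mm` must be positive")
  L <- distal_falloff_mm / COS_RAMP_8020
  lo <- range_mm - modulation_mm
  w <- wepl_mm
  dose <- numeric(length(w))
  ramp_up <- w >= lo - L & w < lo
  dose[ramp_up] <- 0.5 * (1 - cos(pi * (w[ramp_up] - (lo - L)) / L))
  plateau <- w >= lo & w <= range_mm
  dose[plateau] <- 1
  fall <- w > range_mm & w < range_mm + L
  dose[fall] <- 0.5 * (1 + cos(pi * (w[fall] - range_mm) / L))
  dose
}

# cumulative WEPL to every voxel center for a beam travelling along +/- a
# grid axis: exact (sum of full upstream voxels + half the voxel itself)
wepl_grid_axis <- function(rsp, axis, positive) {
  v <- rsp$values
  h <- rsp$spacing[axis]
  perm <- c(axis, setdiff(1:3, axis))
  vp <- aperm(v, perm)
  dp <- dim(vp)
  m <- matrix(vp, nrow = dp[1])
  if (!positive) m <- m[rev(seq_len(dp[1])), , drop = FALSE]
  cs <- apply(m, 2, cumsum)
  w <- (cs - 0.5 * m) * h
  if (!positive) w <- w[rev(seq_len(dp[1])), , drop = FALSE]
  aperm(array(w, dp), order(perm))
}

# WEPL by midpoint ray marching for an arbitrary direction
wepl_grid_march <- function(rsp, d, step = NULL) {
  if (is.null(step)) step <- min(rsp$spacing) / 2
  dmn <- grid_dim(rsp)
  x <- axis_centers(rsp, 1); y <- axis_centers(rsp, 2); z <- axis_centers(rsp, 3)
  px <- array(x, dmn)
  py <- aperm(array(y, dmn[c(2, 1, 3)]), c(2, 1, 3))
  pz <- aperm(array(z, dmn[c(3, 1, 2)]), c(2, 3, 1))
  n_steps <- ceiling(sqrt(sum(((grid_upper(rsp) - rsp$origin))^2)) / step) + 1L
  wepl <- array(0, dmn)
  vals <- rsp$values
  for (k in seq_len(n_steps)) {
    t <- (k - 0.5) * step
    qx <- px - t * d[1]; qy <- py - t * d[2]; qz <- pz - t * d[3]
    ix <- floor((qx - rsp$origin[1]) / rsp$spacing[1]) + 1
    iy <- floor((qy - rsp$origin[2]) / rsp$spacing[2]) + 1
    iz <- floor((qz - rsp$origin[3]) / rsp$spacing[3]) + 1
    ok <- ix >= 1 & ix <= dmn[1] & iy >= 1 & iy <= dmn[2] & iz >= 1 & iz <= dmn[3]
    if (!any(ok)) break
    lin <- ix[ok] + (iy[ok] - 1) * dmn[1] + (iz[ok] - 1) * dmn[1] * dmn[2]
    add <- numeric(length(ok))
    add[ok] <- vals[lin] * step
    wepl <- wepl + array(add, dmn)
  }
  wepl
}

beam_wepl_grid <- function(rsp, d) {
  ax <- which(abs(abs(d) - 1) < 1e-12)
  if (length(ax) == 1 && sum(abs(d) > 1e-12) == 1) {
    wepl_grid_axis(rsp, ax, d[ax] > 0)
  } else {
    wepl_grid_march(rsp, d)
  }
}

# squared lateral distance of every voxel center from a beam's central axis
lateral_sq_grid <- function(grid, iso, d) {
  dmn <- grid_dim(grid)
  x <- axis_centers(grid, 1) - iso[1]
  y <- axis_centers(grid, 2) - iso[2]
  z <- axis_centers(grid, 3) - iso[3]
  px <- array(x, dmn)
  py <- aperm(array(y, dmn[c(2, 1, 3)]), c(2, 1, 3))
  pz <- aperm(array(z, dmn[c(3, 1, 2)]), c(2, 3, 1))
  proj <- px * d[1] + py * d[2] + pz * d[3]
  px^2 + py^2 + pz^2 - proj^2
}

#' Broad-beam SOBP dose calculation on a voxel phantom
#'
#' A deterministic, broad-beam ray-cast engine: for every voxel and beam,
#' the water-equivalent depth from the beam entry to the voxel is computed
#' along the beam direction (exactly, by cumulative summation, for
#' axis-aligned beams; by fine midpoint ray marching otherwise), converted
#' to relative dose through [sobp_depth_dose()], gated by the hard-edged
#' circular aperture, weighted, and summed over beams.  No lateral scatter
#' or penumbra is modelled; this is a declared surrogate for clinical
#' Monte-Carlo or pencil-beam engines.
#'
#' @param phantom `vox_grid` of kind `"hu"` (with `curve`) or `"rsp"`.
#' @param plan a [plan_spec()], or a list of [beam_spec()] objects (any
#'   count) together with `prescription_dose`.
#' @param curve [calibration_curve()] for HU phantoms.
#' @param overrides optional list of `list(record =, mask =)` density
#'   overrides applied before dose calculation.
#' @param prescription_dose used when `plan` is a bare beam list.
#' @param iso_shift rigid setup shift (mm, length 3) added to every beam's
#'   isocenter (used by robustness scenarios).
#' @param rsp_scale global stopping-power scale factor (range scenarios).
#' @param per_beam if `TRUE`, return a list of per-beam dose grids instead
#'   of their sum.
#' @return A dose `vox_grid`, or a list of them when `per_beam = TRUE`.
#' @export
compute_dose <- function(phantom, plan, curve = NULL, overrides = NULL,
                         prescription_dose = NULL, iso_shift = c(0, 0, 0),
                         rsp_scale = 1, per_beam = FALSE) {
  rsp <- as_rsp_grid(phantom, curve)
  if (!is.null(overrides)) {
    for (ov in overrides) rsp <- apply_override(rsp, ov$mask, ov$record)
  }
  if (rsp_scale != 1) rsp$values <- rsp$values * rsp_scale
  if (inherits(plan, "plan_spec")) {
    beams <- plan$beams
    rx <- plan$prescription_dose
  } else {
    beams <- plan
    pw_check(all(vapply(beams, inherits, TRUE, "beam_spec")),
             "`plan` must be a plan_spec or a list of beam_spec objects")
    rx <- if (is.null(prescription_dose)) 100 else prescription_dose
  }
  doses <- lapply(beams, function(b) {
    d <- gantry_direction(b$gantry_angle_deg)
    wepl <- beam_wepl_grid(rsp, d)
    dose <- b$weight * rx *
      sobp_depth_dose(wepl, b$sobp_range_mm, b$sobp_modulation_mm,
                      b$distal_falloff_mm)
    dose <- array(dose, grid_dim(rsp))
    if (is.finite(b$aperture_radius_mm)) {
      lat2 <- lateral_sq_grid(rsp, b$isocenter_mm + iso_shift, d)
      dose[lat2 > b$aperture_radius_mm^2] <- 0
    }
    vox_grid(dose, rsp$spacing, rsp$origin, kind = "dose")
  })
  if (per_beam) return(doses)
  total <- doses[[1]]
  if (length(doses) > 1) {
    for (i in 2:length(doses)) total$values <- total$values + doses[[i]]$values
  }
  total
}

#' Robustness scenario set
#'
#' The 12 uncertainty scenarios used for robustness evaluation: the 6
#' cardinal setup shifts (+/-x, +/-y, +/-z at the setup uncertainty)
#' crossed with the 2 range scalings (stopping power scaled by
#' `1 +/- range_uncertainty_fraction`), plus the nominal scenario kept
#' separately as the first row.
#'
#' @param setup_uncertainty_mm setup shift magnitude (mm).
#' @param range_uncertainty_fraction relative stopping-power scaling.
#' @return A data frame with columns `name`, `dx`, `dy`, `dz`,
#'   `rsp_scale`; 13 rows (nominal first).
#' @export
scenario_set <- function(setup_uncertainty_mm, range_uncertainty_fraction) {
  s <- setup_uncertainty_mm
  shifts <- rbind(c(s, 0, 0), c(-s, 0, 0), c(0, s, 0), c(0, -s, 0),
                  c(0, 0, s), c(0, 0, -s))
  scales <- c(1 - range_uncertainty_fraction, 1 + range_uncertainty_fraction)
  grid <- expand.grid(shift = seq_len(nrow(shifts)), scale = scales)
  out <- data.frame(
    name = c("nominal",
             sprintf("shift%+g%+g%+g_scale%.3f",
                     shifts[grid$shift, 1], shifts[grid$shift, 2],
                     shifts[grid$shift, 3], grid$scale)),
    dx = c(0, shifts[grid$shift, 1]),
    dy = c(0, shifts[grid$shift, 2]),
    dz = c(0, shifts[grid$shift, 3]),
    rsp_scale = c(1, grid$scale),
    stringsAsFactors = FALSE
  )
  out
}

#' Nominal and perturbed dose distributions for robustness evaluation
#'
#' Recomputes the plan dose in every scenario of [scenario_set()]: the
#' setup shift is applied as a rigid isocenter translation and the range
#' uncertainty as a global stopping-power scaling.
#'
#' @inheritParams compute_dose
#' @param plan a [plan_spec()] carrying the uncertainty magnitudes.
#' @return A named list of dose `vox_grid`s, `nominal` first.
#' @export
scenario_doses <- function(phantom, plan, curve = NULL, overrides = NULL) {
  pw_check(inherits(plan, "plan_spec"), "`plan` must be a plan_spec")
  scn <- scenario_set(plan$setup_uncertainty_mm,
                      plan$range_uncertainty_fraction)
  out <- lapply(seq_len(nrow(scn)), function(i) {
    compute_dose(phantom, plan, curve = curve, overrides = overrides,
                 iso_shift = c(scn$dx[i], scn$dy[i], scn$dz[i]),
                 rsp_scale = scn$rsp_scale[i])
  })
  names(out) <- scn$name
  out
}
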