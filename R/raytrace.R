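#' A straight ray segment in world coordinates
#'
#' @param origin_mm numeric length-3 start point (mm).
#' @param direction numeric length-3 direction; normalised internally
#'   (must be non-zero).
#' @param length_mm segment length (mm); `Inf` traces until the ray leaves
#'   the grid.
#' @return An object of class `ray3`.
#' @export
ray3 <- function(origin_mm, direction, length_mm = Inf) {
  pw_check(length(origin_mm) == 3 && all(is.finite(origin_mm)),
           "`origin_mm` must be 3 finite numbers")
  pw_check(length(direction) == 3 && all(is.finite(direction)),
           "`direction` must be 3 finite numbers")
  nrm <- sqrt(sum(direction^2))
  pw_check(nrm > 0, "`direction` must be non-zero")
  pw_check(length_mm > 0, "`length_mm` must be positive")
  structure(list(origin_mm = as.numeric(origin_mm),
                 direction = as.numeric(direction) / nrm,
                 length_mm = length_mm),
            class = "ray3")
}

# Siddon-style exact traversal: parametric crossings of all voxel boundary
# planes within the in-grid, in-segment parameter range.  Returns a list of
# segment lengths and the (i,j,k) voxel index of each segment, or NULL when
# the ray misses the grid.
siddon_segments <- function(grid, ray) {
  o <- ray$origin_mm
  d <- ray$direction
  lo <- grid$origin
  hi <- grid_upper(grid)
  t0 <- 0
  t1 <- ray$length_mm
  for (a in 1:3) {
    if (abs(d[a]) < 1e-14) {
      if (o[a] <= lo[a] || o[a] >= hi[a]) return(NULL)
    } else {
      ta <- (lo[a] - o[a]) / d[a]
      tb <- (hi[a] - o[a]) / d[a]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0 + 1e-12) return(NULL)
  # all boundary-plane crossings inside (t0, t1)
  ts <- c(t0, t1)
  for (a in 1:3) {
    if (abs(d[a]) < 1e-14) next
    planes <- lo[a] + (0:grid_dim(grid)[a]) * grid$spacing[a]
    ta <- (planes - o[a]) / d[a]
    ts <- c(ts, ta[ta > t0 + 1e-12 & ta < t1 - 1e-12])
  }
  ts <- sort(unique(ts))
  mid <- (ts[-length(ts)] + ts[-1]) / 2
  len <- diff(ts)
  pts <- cbind(o[1] + mid * d[1], o[2] + mid * d[2], o[3] + mid * d[3])
  idx <- world_to_index(grid, pts)
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2]) & !is.na(idx[, 3])
  list(lengths = len[keep], index = idx[keep, , drop = FALSE])
}

#' Radiological path length (WEPL) of a ray through a voxel phantom
#'
#' Exact voxel-boundary (Siddon-style) traversal: the water-equivalent path
#' length is the sum over traversed voxel segments of segment length times
#' the voxel's relative stopping power.  With `restrict_mask` given, only
#' the segments inside the mask contribute — this is how a device's WET is
#' read off a CT scan in the planning system.
#'
#' @param phantom a `vox_grid` of kind `"hu"` (converted through `curve`)
#'   or `"rsp"` (used directly).
#' @param ray a [ray3()].
#' @param curve a [calibration_curve()]; required for an HU phantom.
#' @param restrict_mask optional `vox_grid` mask on the same geometry.
#' @return WEPL in mm; 0 with a warning if the ray misses the grid.
#' @export
ray_trace_wet <- function(phantom, ray, curve = NULL, restrict_mask = NULL) {
  rsp <- as_rsp_grid(phantom, curve)
  if (!is.null(restrict_mask)) check_same_grid(rsp, restrict_mask, "restrict_mask")
  seg <- siddon_segments(rsp, ray)
  if (is.null(seg) || length(seg$lengths) == 0) {
    pw_warn("ray does not intersect the grid; WEPL = 0",
            "protonWET_ray_miss_warning")
    return(0)
  }
  vals <- rsp$values[seg$index]
  if (!is.null(restrict_mask)) {
    inside <- restrict_mask$values[seg$index]
    vals <- vals * as.numeric(inside)
  }
  sum(seg$lengths * vals)
}

#' Physical thickness of a structure along a ray
#'
#' Total in-mask intersection length (mm) of the ray with the structure,
#' by exact voxel traversal.
#'
#' @param mask a `vox_grid` mask.
#' @param ray a [ray3()].
#' @return Thickness in mm; 0 with a warning when the ray misses the mask.
#' @export
device_thickness <- function(mask, ray) {
  pw_check(inherits(mask, "vox_grid") && mask$kind == "mask",
           "`mask` must be a vox_grid of kind 'mask'")
  seg <- siddon_segments(mask, ray)
  thick <- 0
  if (!is.null(seg) && length(seg$lengths) > 0) {
    thick <- sum(seg$lengths * as.numeric(mask$values[seg$index]))
  }
  if (thick == 0) {
    pw_warn("ray does not intersect the mask; thickness = 0",
            "protonWET_ray_miss_warning")
  }
  thick
}

#' Planning-system SPR measurement at one device location
#'
#' Emulates the TPS-side measurement: WET is the radiological path length
#' restricted to the device contour along a probe line through the
#' location, the physical thickness is the in-contour intersection length
#' of the same line, and SPR is their ratio.  `n_repeats` averages repeated
#' evaluations; with `jitter_mm > 0` each repeat displaces the probe line
#' laterally by a random offset, emulating the variability of repeated
#' manual measurements (with jitter off the repeats are identical).
#'
#' @param phantom `vox_grid` of kind `"hu"` or `"rsp"`.
#' @param mask device contour (`vox_grid` mask).
#' @param ray probe line, a [ray3()]; by default perpendicular to the
#'   device surface.
#' @param curve [calibration_curve()] (required for an HU phantom).
#' @param n_repeats number of repeated measurements to average.
#' @param jitter_mm standard deviation (mm) of the lateral probe offset per
#'   repeat; 0 for deterministic repeats.
#' @param location_id passed through to the result.
#' @return A [spr_at_location()] measurement.
#' @export
tps_spr_at_location <- function(phantom, mask, ray, curve = NULL,
                                n_repeats = 3L, jitter_mm = 0,
                                location_id = NA) {
  pw_check(n_repeats >= 1, "`n_repeats` must be at least 1")
  check_same_grid(phantom, mask)
  # a lateral frame perpendicular to the probe direction
  d <- ray$direction
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * ref[3] - d[3] * ref[2],
         d[3] * ref[1] - d[1] * ref[3],
         d[1] * ref[2] - d[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  wets <- numeric(n_repeats)
  thicks <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    off <- if (jitter_mm > 0) stats::rnorm(2, sd = jitter_mm) else c(0, 0)
    rr <- ray3(ray$origin_mm + off[1] * u + off[2] * v, d, ray$length_mm)
    wets[r] <- ray_trace_wet(phantom, rr, curve, restrict_mask = mask)
    thicks[r] <- suppressWarnings(device_thickness(mask, rr))
  }
  wet <- mean(wets)
  thick <- mean(thicks)
  pw_check(thick > 0, "probe line does not cross the device contour",
           "protonWET_zero_thickness_error")
  spr_at_location(wet, thick, location_id = location_id)
}

#' Compare planning-system and measured device SPR
#'
#' Produces the per-device comparison row: percent SPR difference and the
#' resulting WET error.  When both results carry the same number of
#' per-location measurements, the percent difference is the mean of the
#' per-location percent differences (the convention used when each marked
#' location is an independent paired measurement); otherwise it is computed
#' from the device means.  `wet_diff_mm = (tps_spr - measured_spr) *
#' thickness_mm` uses the mean device thickness unless given.
#'
#' @param tps [device_spr()] result from the planning system.
#' @param measured [device_spr()] result from the range-shift measurement.
#' @param thickness_mm physical thickness used for the WET error; defaults
#'   to the measured result's mean thickness.
#' @return An object of class `spr_comparison` with `tps_spr`,
#'   `measured_spr`, `percent_diff`, `wet_diff_mm`, and per-location sd
#'   where available.
#' @export
compare_spr <- function(tps, measured, thickness_mm = NULL) {
  pw_check(inherits(tps, "device_spr_result") &&
             inherits(measured, "device_spr_result"),
           "`tps` and `measured` must be device_spr_result objects")
  pw_check(identical(tps$device, measured$device),
           "comparison requires results for the same device")
  pw_check(measured$mean_spr > 0, "measured SPR must be positive")
  if (is.null(thickness_mm)) thickness_mm <- measured$mean_thickness_mm
  paired <- length(tps$sprs) == length(measured$sprs) && length(tps$sprs) >= 1
  if (paired) {
    pct_loc <- 100 * (tps$sprs - measured$sprs) / measured$sprs
    percent_diff <- mean(pct_loc)
    percent_sd <- if (length(pct_loc) >= 2) stats::sd(pct_loc) else NA_real_
  } else {
    percent_diff <- 100 * (tps$mean_spr - measured$mean_spr) / measured$mean_spr
    percent_sd <- NA_real_
  }
  structure(list(device = tps$device,
                 tps_spr = tps$mean_spr,
                 measured_spr = measured$mean_spr,
                 percent_diff = percent_diff,
                 percent_sd = percent_sd,
                 wet_diff_mm = (tps$mean_spr - measured$mean_spr) * thickness_mm,
                 thickness_mm = thickness_mm),
            class = "spr_comparison")
}

#' @export
print.spr_comparison <- function(x, ...) {
  cat(sprintf("<spr_comparison> %s: TPS %.3f vs measured %.3f (%+.1f%%), WET error %+.2f mm\n",
              x$device, x$tps_spr, x$measured_spr, x$percent_diff, x$wet_diff_mm))
  invisible(x)
}
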