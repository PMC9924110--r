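#' Integrated depth-dose curve
#'
#' A sampled IDD: laterally integrated signal versus depth, as recorded by
#' a multilayer ionization chamber or exported from a planning system.
#'
#' @param depths_mm strictly increasing sample depths (mm), length >= 10.
#' @param signal non-negative readings, same length, with `max(signal) > 0`.
#' @return An object of class `depth_dose_curve`.
#' @export
depth_dose_curve <- function(depths_mm, signal) {
  pw_check(length(depths_mm) >= 10, "a curve needs at least 10 samples")
  pw_check(length(signal) == length(depths_mm),
           "`signal` and `depths_mm` must have equal length")
  pw_check(all(is.finite(depths_mm)) && all(diff(depths_mm) > 0),
           "`depths_mm` must be finite and strictly increasing",
           "protonWET_monotonicity_error")
  pw_check(all(is.finite(signal)) && all(signal >= 0),
           "`signal` must be finite and non-negative")
  pw_check(max(signal) > 0, "`signal` must not be identically zero")
  structure(list(depths_mm = as.numeric(depths_mm),
                 signal = as.numeric(signal)),
            class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("<depth_dose_curve> %d samples, depths [%g, %g] mm, peak %.4g at %.1f mm\n",
              length(x$depths_mm), min(x$depths_mm), max(x$depths_mm),
              max(x$signal), x$depths_mm[which.max(x$signal)]))
  invisible(x)
}

#' Most distal depth at which a curve crosses a fraction of its maximum
#'
#' The distal R80/R90 convention: the fraction refers to the curve MAXIMUM
#' (not the entrance plateau), and the crossing is sought on the distal
#' falloff — the most distal depth where the linearly interpolated signal
#' equals `fraction * max(signal)` on a decreasing segment.  A spurious
#' shallow dip (noise) therefore never changes the result.  An exact hit on
#' a sample returns that sample's depth.
#'
#' @param curve a [depth_dose_curve()].
#' @param fraction threshold as a fraction of the maximum, in (0, 1).
#' @return Depth in mm, at or beyond the depth of the maximum.
#' @export
distal_threshold_depth <- function(curve, fraction) {
  pw_check(inherits(curve, "depth_dose_curve"), "`curve` must be a depth_dose_curve")
  pw_check(fraction > 0 && fraction < 1, "`fraction` must lie in (0, 1)")
  s <- curve$signal
  d <- curve$depths_mm
  n <- length(s)
  target <- fraction * max(s)
  i_max <- which.max(s)
  if (i_max == n) {
    pw_abort("curve maximum at the deepest sample: distal falloff truncated",
             "protonWET_range_not_found_error")
  }
  # scan distal-to-proximal for the most distal decreasing segment that
  # brackets the threshold
  for (j in seq(n - 1L, i_max, by = -1L)) {
    if (s[j] > s[j + 1L] && s[j] >= target && s[j + 1L] <= target) {
      if (s[j] == target) return(d[j])
      return(d[j] + (s[j] - target) / (s[j] - s[j + 1L]) * (d[j + 1L] - d[j]))
    }
  }
  pw_abort(sprintf("no distal crossing of %.0f%% of maximum found (truncated curve?)",
                   100 * fraction),
           "protonWET_range_not_found_error")
}

#' Distal R80 and R90 of a depth-dose curve
#'
#' @param curve a [depth_dose_curve()].
#' @return A list of class `range_metrics` with `r80_mm` and `r90_mm`
#'   (`r90_mm <= r80_mm`: on the falling distal edge the 90% crossing is
#'   shallower than the 80% crossing).
#' @export
range_metrics <- function(curve) {
  r80 <- distal_threshold_depth(curve, 0.8)
  r90 <- distal_threshold_depth(curve, 0.9)
  structure(list(r80_mm = r80, r90_mm = r90), class = "range_metrics")
}

#' Water-equivalent thickness from a reference/sample IDD pair
#'
#' The WET of the object placed upstream of the detector is the shift in
#' proton range from the reference (unperturbed) curve to the sample curve,
#' averaging the shifts of the distal R80 and R90:
#' `wet = ((r80_ref - r80_sam) + (r90_ref - r90_sam)) / 2`.
#'
#' A negative result (sample deeper than reference) usually means the two
#' curves were swapped; it is returned with a warning rather than an error
#' so that QA misuse remains visible.
#'
#' @param reference,sample [depth_dose_curve()] objects without and with
#'   the device in the beam path.
#' @return WET in mm.
#' @export
wet_from_curves <- function(reference, sample) {
  ref <- range_metrics(reference)
  sam <- range_metrics(sample)
  wet <- ((ref$r80_mm - sam$r80_mm) + (ref$r90_mm - sam$r90_mm)) / 2
  if (wet < 0) {
    pw_warn(sprintf("negative WET (%.2f mm): reference and sample curves may be swapped",
                    wet),
            "protonWET_negative_wet_warning")
  }
  wet
}

#' Per-location SPR from measured WET and physical thickness
#'
#' @param wet_mm measured water-equivalent thickness (mm).
#' @param thickness_mm physical thickness along the beam (mm, > 0),
#'   typically read off the CT scan.
#' @param location_id optional identifier of the BB-marked location.
#' @return An object of class `wet_measurement` with `wet_mm`,
#'   `thickness_mm` and `spr = wet_mm / thickness_mm`.
#' @export
spr_at_location <- function(wet_mm, thickness_mm, location_id = NA) {
  pw_check(is.finite(thickness_mm) && thickness_mm > 0,
           "`thickness_mm` must be positive")
  structure(list(location_id = location_id,
                 wet_mm = as.numeric(wet_mm),
                 thickness_mm = as.numeric(thickness_mm),
                 spr = as.numeric(wet_mm) / as.numeric(thickness_mm)),
            class = "wet_measurement")
}

#' Aggregate per-location SPR measurements for one device
#'
#' The device SPR is the arithmetic mean of the per-location SPR values;
#' the standard deviation is reported when at least two locations were
#' sampled (NA for a single location).
#'
#' @param measurements list of [spr_at_location()] results (length >= 1).
#' @param device name of the device.
#' @return An object of class `device_spr_result` with `mean_spr`,
#'   `spr_sd`, the measurement list, and per-location vectors.
#' @export
device_spr <- function(measurements, device = "device") {
  pw_check(length(measurements) >= 1, "at least one measurement is required")
  pw_check(all(vapply(measurements, inherits, TRUE, "wet_measurement")),
           "all elements must be wet_measurement objects")
  sprs <- vapply(measurements, `[[`, 0, "spr")
  structure(list(device = device,
                 measurements = measurements,
                 sprs = sprs,
                 mean_spr = mean(sprs),
                 spr_sd = if (length(sprs) >= 2) stats::sd(sprs) else NA_real_,
                 mean_thickness_mm = mean(vapply(measurements, `[[`, 0, "thickness_mm")),
                 mean_wet_mm = mean(vapply(measurements, `[[`, 0, "wet_mm"))),
            class = "device_spr_result")
}

#' @export
print.device_spr_result <- function(x, ...) {
  cat(sprintf("<device_spr_result> %s: SPR %.3f%s over %d location(s)\n",
              x$device, x$mean_spr,
              if (is.na(x$spr_sd)) "" else sprintf(" +/- %.3f", x$spr_sd),
              length(x$sprs)))
  invisible(x)
}
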