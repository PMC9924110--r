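#' CT calibration curve: HU to mass density to relative stopping power
#'
#' Clinical proton dose calculation converts CT numbers to mass density with
#' a scanner-specific piecewise-linear table and then density to relative
#' stopping power (RSP, the stopping power of the material relative to
#' water).  Both stages are represented here as monotone node tables and
#' evaluated by linear interpolation; HU (or density) outside the table
#' domain is clamped to the end nodes, mirroring planning-system behaviour.
#'
#' A single-stage HU-to-RSP table is also accepted: supply `hu` and `rsp`
#' and omit the density tables, in which case the density stage is the
#' identity on the interpolated RSP.
#'
#' @param hu strictly increasing numeric vector of HU nodes.
#' @param density mass density (g/cm^3) at each HU node; non-decreasing.
#' @param density_nodes,rsp second-stage table mapping density to RSP;
#'   `density_nodes` strictly increasing, `rsp` non-decreasing.  If both are
#'   `NULL` and `rsp` has the length of `hu`, the curve is single-stage.
#' @return An object of class `calibration_curve`.
#' @examples
#' cal <- calibration_curve(hu = c(-1000, 0, 1000),
#'                          density = c(0.00121, 1.0, 1.59),
#'                          density_nodes = c(0.00121, 1.0, 1.59),
#'                          rsp = c(0.00107, 1.0, 1.49))
#' hu_to_rsp(0, cal)
#' @export
calibration_curve <- function(hu, density = NULL, density_nodes = NULL,
                              rsp = NULL) {
  pw_check(length(hu) >= 2 && all(diff(hu) > 0),
           "`hu` nodes must be strictly increasing (length >= 2)",
           "protonWET_monotonicity_error")
  if (is.null(density) && !is.null(rsp)) {
    # single-stage HU -> RSP table
    pw_check(length(rsp) == length(hu), "`rsp` must match `hu` in length")
    pw_check(all(rsp >= 0) && all(diff(rsp) >= 0),
             "`rsp` must be non-negative and non-decreasing",
             "protonWET_monotonicity_error")
    out <- list(hu = as.numeric(hu), density = as.numeric(rsp),
                density_nodes = as.numeric(rsp), rsp = as.numeric(rsp),
                single_stage = TRUE)
    return(structure(out, class = "calibration_curve"))
  }
  pw_check(!is.null(density) && length(density) == length(hu),
           "`density` must match `hu` in length")
  pw_check(all(density >= 0) && all(diff(density) >= 0),
           "`density` must be non-negative and non-decreasing",
           "protonWET_monotonicity_error")
  if (is.null(density_nodes)) {
    # density stage present but no RSP table: treat RSP == density
    density_nodes <- sort(unique(density))
    rsp <- density_nodes
  }
  pw_check(length(density_nodes) >= 2 && all(diff(density_nodes) > 0),
           "`density_nodes` must be strictly increasing",
           "protonWET_monotonicity_error")
  pw_check(length(rsp) == length(density_nodes),
           "`rsp` must match `density_nodes` in length")
  pw_check(all(rsp >= 0) && all(diff(rsp) >= 0),
           "`rsp` must be non-negative and non-decreasing",
           "protonWET_monotonicity_error")
  structure(list(hu = as.numeric(hu), density = as.numeric(density),
                 density_nodes = as.numeric(density_nodes),
                 rsp = as.numeric(rsp), single_stage = FALSE),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d HU nodes [%g, %g]%s\n",
              length(x$hu), min(x$hu), max(x$hu),
              if (x$single_stage) " (single-stage HU->RSP)" else
                sprintf(", %d density nodes", length(x$density_nodes))))
  invisible(x)
}

# clamped piecewise-linear interpolation
interp_clamped <- function(x, xs, ys) {
  stats::approx(xs, ys, xout = x, method = "linear", rule = 2, ties = "ordered")$y
}

#' @rdname calibration_curve
#' @param x HU (for `hu_to_density`, `hu_to_rsp`) or mass density
#'   (for `density_to_rsp`); vectorized.
#' @param curve a `calibration_curve`.
#' @export
hu_to_density <- function(x, curve) {
  pw_check(inherits(curve, "calibration_curve"), "`curve` must be a calibration_curve")
  interp_clamped(x, curve$hu, curve$density)
}

#' @rdname calibration_curve
#' @export
density_to_rsp <- function(x, curve) {
  pw_check(inherits(curve, "calibration_curve"), "`curve` must be a calibration_curve")
  if (curve$single_stage) return(as.numeric(x))
  interp_clamped(x, curve$density_nodes, curve$rsp)
}

#' @rdname calibration_curve
#' @export
hu_to_rsp <- function(x, curve) {
  if (isTRUE(curve$single_stage)) {
    return(interp_clamped(x, curve$hu, curve$rsp))
  }
  density_to_rsp(hu_to_density(x, curve), curve)
}

#' Invert the calibration: HU whose RSP is closest to a target
#'
#' Used by the synthetic-data generator to pick the CT number a virtual
#' scanner should assign so the planning system derives a prescribed RSP.
#' The composed HU-to-RSP map is monotone non-decreasing; plateaus are
#' resolved to the lowest HU attaining the value.
#'
#' @param rsp target relative stopping power (scalar).
#' @param curve a [calibration_curve()].
#' @return HU value (clamped to the table domain).
#' @export
rsp_to_hu <- function(rsp, curve) {
  pw_check(length(rsp) == 1 && is.finite(rsp), "`rsp` must be a finite scalar")
  lo <- min(curve$hu); hi <- max(curve$hu)
  r_lo <- hu_to_rsp(lo, curve); r_hi <- hu_to_rsp(hi, curve)
  pw_check(rsp >= r_lo - 1e-12 && rsp <= r_hi + 1e-12,
           "target RSP outside the calibration curve's range")
  if (rsp <= r_lo) return(lo)
  if (rsp >= r_hi) return(hi)
  # composed map is piecewise linear and non-decreasing
  stats::uniroot(function(h) hu_to_rsp(h, curve) - rsp, c(lo, hi),
                 tol = 1e-10)$root
}

#' Bundled clinical-style calibration curve
#'
#' A synthetic stand-in for a scanner calibration, with nodes at air, lung,
#' adipose, water, muscle, and bone surrogates.  The node values are
#' plausible for a 120-kVp scan but are a fixture of this package, not a
#' measured clinical curve; use [read_calibration_csv()] to load a real one.
#'
#' @return A [calibration_curve()].
#' @export
default_calibration <- function() {
  calibration_curve(
    hu      = c(-1000, -700, -98, 0, 40, 240, 1000, 3000),
    density = c(0.00121, 0.30, 0.93, 1.000, 1.04, 1.16, 1.61, 2.80),
    density_nodes = c(0.00121, 0.30, 0.93, 1.000, 1.04, 1.16, 1.61, 2.80),
    rsp     = c(0.00107, 0.30, 0.95, 1.000, 1.03, 1.12, 1.49, 2.45)
  )
}
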