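#' Parameters of the analytic pristine Bragg-peak / virtual MLIC model
#'
#' Describes both the beam model (an analytic pristine Bragg curve) and the
#' detector that samples it: a multilayer ionization chamber (MLIC) of
#' `n_chambers` plane-parallel chambers at `chamber_pitch_mm` spacing.
#' Chamber `i` (0-based) is centred at depth `(i + 0.5) * chamber_pitch_mm`.
#' The defaults emulate a 180-chamber, 2-mm-pitch stack recording a
#' 200-MeV pencil beam, whose distal R80 in water is taken as 259 mm.
#'
#' The pristine depth-dose is a power-law stopping model
#' `d0(z) = (R - z)^(-0.435) + b (R - z)^(0.565)` for `z < R`, convolved
#' with a Gaussian of width `straggling_sigma_mm` to represent range
#' straggling.  The mixing coefficient `b` is solved so the entrance-to-peak
#' signal ratio equals `plateau_entrance_ratio`, and the curve is shifted so
#' its distal R80 falls exactly at `nominal_range_mm`.
#'
#' @param nominal_range_mm depth in water (mm) of the distal R80 of the
#'   pristine peak.
#' @param straggling_sigma_mm Gaussian range-straggling width (mm).
#' @param plateau_entrance_ratio entrance signal / peak signal, in (0, 1).
#' @param chamber_pitch_mm detector sampling interval (mm).
#' @param n_chambers number of chambers.
#' @param noise_cv per-chamber multiplicative noise coefficient of
#'   variation (0 disables noise).
#' @param seed RNG seed used when noise is enabled.
#' @return A validated list of class `bragg_params`.
#' @export
bragg_params <- function(nominal_range_mm = 259,
                         straggling_sigma_mm = 3.1,
                         plateau_entrance_ratio = 0.30,
                         chamber_pitch_mm = 2,
                         n_chambers = 180L,
                         noise_cv = 0.005,
                         seed = 1L) {
  pw_check(nominal_range_mm > 0, "`nominal_range_mm` must be positive")
  pw_check(straggling_sigma_mm > 0 && straggling_sigma_mm < nominal_range_mm,
           "`straggling_sigma_mm` must lie in (0, nominal_range_mm)")
  pw_check(plateau_entrance_ratio > 0 && plateau_entrance_ratio < 1,
           "`plateau_entrance_ratio` must lie in (0, 1)")
  pw_check(chamber_pitch_mm > 0, "`chamber_pitch_mm` must be positive")
  pw_check(n_chambers >= 10, "`n_chambers` must be at least 10")
  pw_check(noise_cv >= 0, "`noise_cv` must be non-negative")
  pw_check(n_chambers * chamber_pitch_mm > nominal_range_mm,
           "detector span (n_chambers * pitch) must exceed nominal_range_mm")
  structure(list(nominal_range_mm = nominal_range_mm,
                 straggling_sigma_mm = straggling_sigma_mm,
                 plateau_entrance_ratio = plateau_entrance_ratio,
                 chamber_pitch_mm = chamber_pitch_mm,
                 n_chambers = as.integer(n_chambers),
                 noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "bragg_params")
}

# cell-averaged singular term of the power-law depth dose:
# mean over [zl, zr] of (R - z)^(-0.435), with the primitive
# (R - z)^(0.565) / 0.565 (integrable singularity at z = R).
power_term_cellavg <- function(z, h, R, p_exp = 0.565) {
  zl <- z - h / 2
  zr <- pmin(z + h / 2, R)
  out <- numeric(length(z))
  in_range <- zl < R
  a <- pmax(R - zr[in_range], 0)
  b <- R - zl[in_range]
  out[in_range] <- (b^p_exp - a^p_exp) / (p_exp * (zr[in_range] - zl[in_range]))
  out
}

# build the convolved curve on a fine grid for a given mixing coefficient b
bragg_raw_curve <- function(R, sigma, b, h, z_max) {
  z <- seq(0, z_max, by = h)
  d0 <- power_term_cellavg(z, h, R)
  smooth_term <- ifelse(z < R, (R - z)^0.565, 0)
  d0 <- d0 + b * smooth_term
  half <- ceiling(6 * sigma / h)
  kz <- (-half:half) * h
  kern <- stats::dnorm(kz, sd = sigma)
  kern <- kern / sum(kern)
  # direct FFT-free convolution via stats::filter would drop edges; pad instead
  n <- length(z)
  padded <- c(rep(d0[1], half), d0, rep(0, half))
  sm <- stats::convolve(padded, rev(kern), type = "open")
  # "open" convolution of length (n + 2*half) with (2*half + 1) kernel:
  # the aligned output starts at index 2*half + 1
  sig <- sm[(2 * half + 1):(2 * half + n)]
  list(z = z, signal = sig)
}

#' Build the analytic Bragg-curve model
#'
#' Constructs the pristine depth-dose function once (fine-grid power-law +
#' Gaussian straggling convolution, entrance-ratio calibration, exact R80
#' alignment) so that repeated calls to [generate_idd()] are cheap.
#'
#' @param params a [bragg_params()] object.
#' @param fine_step_mm resolution of the internal fine grid (mm).
#' @return An object of class `bragg_model` containing `fun(z)`, the
#'   pristine signal normalised to a peak of 1, plus the fitted mixing
#'   coefficient and the peak depth.
#' @export
bragg_model <- function(params, fine_step_mm = 0.02) {
  pw_check(inherits(params, "bragg_params"), "`params` must be bragg_params")
  R <- params$nominal_range_mm
  sigma <- params$straggling_sigma_mm
  span <- params$n_chambers * params$chamber_pitch_mm
  z_max <- max(R, span) + 8 * sigma + 5

  entrance_ratio <- function(b) {
    cur <- bragg_raw_curve(R, sigma, b, fine_step_mm, z_max)
    cur$signal[1] / max(cur$signal)
  }
  target <- params$plateau_entrance_ratio
  pw_check(entrance_ratio(0) < target,
           "plateau_entrance_ratio below the minimum attainable by the peak alone is required; increase it")
  b_hi <- 1e-4
  while (entrance_ratio(b_hi) < target && b_hi < 1e6) b_hi <- b_hi * 4
  pw_check(b_hi < 1e6, "could not attain the requested plateau_entrance_ratio")
  b <- stats::uniroot(function(bb) entrance_ratio(bb) - target,
                      c(0, b_hi), tol = 1e-8)$root

  cur <- bragg_raw_curve(R, sigma, b, fine_step_mm, z_max)
  sig <- pmax(cur$signal, 0) / max(cur$signal)  # FFT convolution can ring slightly below 0
  raw_curve <- depth_dose_curve(cur$z, sig)
  r80_raw <- distal_threshold_depth(raw_curve, 0.8)
  shift <- r80_raw - R            # evaluate at z + shift so final R80 == R
  fun_raw <- stats::approxfun(cur$z, sig, yleft = sig[1], yright = 0)
  fun <- function(z) {
    zz <- z + shift
    out <- fun_raw(zz)
    out[zz < 0] <- sig[1]
    out
  }
  peak_depth <- cur$z[which.max(sig)] - shift
  structure(list(params = params, fun = fun, mixing_b = b,
                 peak_depth_mm = peak_depth, r80_shift_mm = shift,
                 fine_step_mm = fine_step_mm),
            class = "bragg_model")
}

#' @export
print.bragg_model <- function(x, ...) {
  cat(sprintf("<bragg_model> R80 = %g mm, sigma = %g mm, peak at %.2f mm, entrance/peak = %.3f\n",
              x$params$nominal_range_mm, x$params$straggling_sigma_mm,
              x$peak_depth_mm, x$params$plateau_entrance_ratio))
  invisible(x)
}

#' Simulate an integrated depth-dose curve on the virtual MLIC
#'
#' Evaluates the pristine analytic Bragg curve at the chamber-centre depths
#' after an exact depth shift of `upstream_wet_mm` — i.e. placing a device
#' of that water-equivalent thickness upstream shifts the whole curve
#' shallower by exactly that amount (`signal(z) = pristine(z +
#' upstream_wet_mm)`).  This models thin, low-density devices for which the
#' change in scatter and straggling is negligible.  If `params$noise_cv >
#' 0`, independent multiplicative Gaussian noise is applied per chamber.
#'
#' @param params a [bragg_params()] object, or a prebuilt [bragg_model()]
#'   (recommended when generating many curves).
#' @param upstream_wet_mm water-equivalent thickness (mm, >= 0) of material
#'   upstream of the detector.
#' @param noise override of `params$noise_cv` (optional).
#' @param seed override of `params$seed` (optional).
#' @return A [depth_dose_curve()] sampled at chamber centres.
#' @export
generate_idd <- function(params, upstream_wet_mm = 0, noise = NULL,
                         seed = NULL) {
  model <- if (inherits(params, "bragg_model")) params else bragg_model(params)
  p <- model$params
  pw_check(upstream_wet_mm >= 0, "`upstream_wet_mm` must be non-negative")
  depths <- (seq_len(p$n_chambers) - 0.5) * p$chamber_pitch_mm
  shifted_r80 <- p$nominal_range_mm - upstream_wet_mm
  if (shifted_r80 + 3 * p$straggling_sigma_mm > max(depths)) {
    pw_abort("shifted distal falloff exits the detector span",
             "protonWET_range_truncation_error")
  }
  pw_check(shifted_r80 > min(depths) + 3 * p$straggling_sigma_mm,
           "upstream WET so large the peak leaves the detector",
           "protonWET_range_truncation_error")
  sig <- model$fun(depths + upstream_wet_mm)
  cv <- if (is.null(noise)) p$noise_cv else noise
  if (cv > 0) {
    if (!is.null(seed)) set.seed(seed) else set.seed(p$seed)
    sig <- sig * (1 + cv * stats::rnorm(length(sig)))
    sig <- pmax(sig, 0)
  }
  depth_dose_curve(depths, sig)
}
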