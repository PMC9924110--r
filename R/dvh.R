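mask_doses <- function(dose, mask) {
  pw_check(inherits(dose, "vox_grid") && dose$kind == "dose",
           "`dose` must be a vox_grid of kind 'dose'")
  check_same_grid(dose, mask)
  pw_check(any(mask$values), "structure mask is empty",
           "protonWET_empty_mask_error")
  dose$values[mask$values]
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose level.
#' The curve starts at 1.0 at dose 0 and is monotone non-increasing.
#' Binning is used only for the curve; the scalar metrics ([v_at()],
#' [d_at()], [dose_max_pct()], [dose_mean_pct()]) use exact voxel counts.
#'
#' @param dose a dose `vox_grid`.
#' @param mask structure mask on the same geometry (non-empty).
#' @param rx prescription dose (sets the default bin range).
#' @param n_bins number of bins (default 1000 from 0 to 110% of `rx`).
#' @return A data frame with `dose` (bin edges) and `volume_fraction`.
#' @export
cumulative_dvh <- function(dose, mask, rx, n_bins = 1000L) {
  d <- mask_doses(dose, mask)
  edges <- seq(0, 1.1 * rx, length.out = n_bins + 1L)
  frac <- vapply(edges, function(e) mean(d >= e), 0)
  data.frame(dose = edges, volume_fraction = frac)
}

#' DVH point metrics
#'
#' `v_at()` is the percent of the structure volume receiving at least
#' `threshold_pct` of the prescription.  `d_at()` is the largest dose
#' (expressed as percent of prescription) received by at least
#' `volume_pct` of the volume — with discrete voxels, the k-th largest
#' voxel dose with `k = ceiling(volume_pct/100 * n)`.  `dose_max_pct()` /
#' `dose_mean_pct()` are the maximum / mean voxel dose as percent of
#' prescription.
#'
#' @param dose a dose `vox_grid`.
#' @param mask structure mask (non-empty, same geometry).
#' @param rx prescription dose.
#' @param threshold_pct dose threshold as percent of prescription.
#' @param volume_pct volume level in (0, 100].
#' @return A percentage (volume for `v_at`, dose for the others).
#' @export
v_at <- function(dose, mask, rx, threshold_pct = 95) {
  d <- mask_doses(dose, mask)
  100 * mean(d >= threshold_pct / 100 * rx)
}

#' @rdname v_at
#' @export
d_at <- function(dose, mask, rx, volume_pct = 95) {
  pw_check(volume_pct > 0 && volume_pct <= 100,
           "`volume_pct` must lie in (0, 100]")
  d <- mask_doses(dose, mask)
  k <- ceiling(volume_pct / 100 * length(d))
  100 * sort(d, decreasing = TRUE)[k] / rx
}

#' @rdname v_at
#' @export
dose_max_pct <- function(dose, mask, rx) 100 * max(mask_doses(dose, mask)) / rx

#' @rdname v_at
#' @export
dose_mean_pct <- function(dose, mask, rx) 100 * mean(mask_doses(dose, mask)) / rx

#' RTOG conformity index
#'
#' Volume enclosed by the prescription (100%) isodose, counted over the
#' whole grid, divided by the target volume.
#'
#' @param dose a dose `vox_grid`.
#' @param ctv_mask target mask (non-empty).
#' @param rx prescription dose.
#' @return Dimensionless index >= 0.
#' @export
conformity_index <- function(dose, ctv_mask, rx) {
  check_same_grid(dose, ctv_mask)
  n_ctv <- sum(ctv_mask$values)
  pw_check(n_ctv > 0, "target mask is empty", "protonWET_empty_mask_error")
  sum(dose$values >= rx) / n_ctv
}

#' Standard DVH metric set for one structure
#'
#' @inheritParams conformity_index
#' @param mask structure mask.
#' @param with_ci include the conformity index (targets only).
#' @return A list of class `dvh_metrics`: `v95_pct`, `d95_pct`,
#'   `max_dose_pct`, `mean_dose_pct`, and `conformity_index` (NA for
#'   non-target structures).
#' @export
dvh_metrics <- function(dose, mask, rx, with_ci = TRUE) {
  structure(list(
    v95_pct = v_at(dose, mask, rx, 95),
    d95_pct = d_at(dose, mask, rx, 95),
    max_dose_pct = dose_max_pct(dose, mask, rx),
    mean_dose_pct = dose_mean_pct(dose, mask, rx),
    conformity_index = if (with_ci) conformity_index(dose, mask, rx) else NA_real_
  ), class = "dvh_metrics")
}

#' Worst-case DVH metrics over robustness scenarios
#'
#' Per-metric extremum across the scenario set: the minimum over scenarios
#' for V95, D95, mean dose and conformity index (coverage can only be
#' hurt), and the maximum for the maximum dose.  This is scenario-level
#' worst-case evaluation, not a voxel-wise worst-case dose.
#'
#' @param metric_list non-empty list of [dvh_metrics()] (one per
#'   scenario, nominal included).
#' @return A `dvh_metrics` object of the worst-case values.
#' @export
worst_case_metrics <- function(metric_list) {
  pw_check(length(metric_list) >= 1, "at least one scenario is required")
  pw_check(all(vapply(metric_list, inherits, TRUE, "dvh_metrics")),
           "all elements must be dvh_metrics objects")
  pick <- function(field, fun) fun(vapply(metric_list, `[[`, 0, field))
  structure(list(
    v95_pct = pick("v95_pct", min),
    d95_pct = pick("d95_pct", min),
    max_dose_pct = pick("max_dose_pct", max),
    mean_dose_pct = pick("mean_dose_pct", min),
    conformity_index = pick("conformity_index", min)
  ), class = "dvh_metrics")
}

#' Beam-specific target coverage metrics
#'
#' Evaluates each beam's dose distribution against `rx / n_beams` as its
#' per-beam prescription (equal weighting among beams is assumed, so each
#' beam of an equally weighted plan is expected to deliver its share of
#' the prescription to the target).
#'
#' @param beam_doses list of per-beam dose `vox_grid`s (length >= 2), as
#'   returned by [compute_dose()] with `per_beam = TRUE` on an
#'   equal-weight plan.
#' @param ctv_mask target mask.
#' @param rx plan prescription dose.
#' @return A list of [dvh_metrics()], one per beam.
#' @export
beam_specific_metrics <- function(beam_doses, ctv_mask, rx) {
  pw_check(length(beam_doses) >= 2, "at least two beams are required")
  rx_b <- rx / length(beam_doses)
  lapply(beam_doses, function(d) dvh_metrics(d, ctv_mask, rx_b))
}
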