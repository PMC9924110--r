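#' Summarise a set of device SPR comparisons
#'
#' Builds the per-device comparison table (TPS SPR, measured SPR, percent
#' difference, WET error) and its summary statistics: mean, minimum and
#' maximum of the SPR percent difference, and the largest absolute WET
#' error.  The summary is always recomputable from the rows.
#'
#' @param comparisons a non-empty list of [compare_spr()] results, or a
#'   data frame with columns `device`, `tps_spr`, `measured_spr`,
#'   `spr_pct_diff`, `wet_diff_mm` (e.g. [device_spr_reference()]).
#' @return A list of class `table1_summary` with `rows` (data frame),
#'   `mean_pct_diff`, `min_pct_diff`, `max_pct_diff`,
#'   `max_abs_wet_diff_mm`.
#' @export
summarize_table1 <- function(comparisons) {
  if (is.data.frame(comparisons)) {
    need <- c("device", "tps_spr", "measured_spr", "spr_pct_diff", "wet_diff_mm")
    pw_check(all(need %in% names(comparisons)),
             sprintf("data frame must have columns: %s", paste(need, collapse = ", ")),
             "protonWET_malformed_header_error")
    pw_check(nrow(comparisons) >= 1, "at least one comparison row is required")
    rows <- comparisons[, need]
  } else {
    pw_check(length(comparisons) >= 1, "at least one comparison is required")
    pw_check(all(vapply(comparisons, inherits, TRUE, "spr_comparison")),
             "all elements must be spr_comparison objects")
    rows <- data.frame(
      device = vapply(comparisons, `[[`, "", "device"),
      tps_spr = vapply(comparisons, `[[`, 0, "tps_spr"),
      measured_spr = vapply(comparisons, `[[`, 0, "measured_spr"),
      spr_pct_diff = vapply(comparisons, `[[`, 0, "percent_diff"),
      wet_diff_mm = vapply(comparisons, `[[`, 0, "wet_diff_mm")
    )
  }
  structure(list(rows = rows,
                 mean_pct_diff = mean(rows$spr_pct_diff),
                 min_pct_diff = min(rows$spr_pct_diff),
                 max_pct_diff = max(rows$spr_pct_diff),
                 max_abs_wet_diff_mm = max(abs(rows$wet_diff_mm))),
            class = "table1_summary")
}

#' @export
print.table1_summary <- function(x, ...) {
  cat("Device SPR comparison summary\n")
  print(x$rows, row.names = FALSE)
  cat(sprintf("\nSPR %%diff: mean %.1f%%, range %.1f%% to %.1f%%; max |WET error| %.1f mm\n",
              x$mean_pct_diff, x$min_pct_diff, x$max_pct_diff,
              x$max_abs_wet_diff_mm))
  invisible(x)
}

#' Published benchmark of TPS-estimated versus measured device SPR
#'
#' A transcription of a published clinical benchmark comparing
#' planning-system-estimated and multilayer-ionization-chamber-measured
#' SPR for nine proton immobilization devices (cushions, vacuum bags,
#' dental putty, comfort sheets, a bite block, and a base-of-skull
#' insert).  Percent differences are per-location means; single-location
#' devices have `NA` standard deviations.  Shipped so the reporting layer
#' can be exercised and checked against the published summary without
#' re-running measurements.
#'
#' @return A data frame with one row per device.
#' @export
device_spr_reference <- function() {
  path <- system.file("extdata", "device_spr_reference.csv",
                      package = "protonWET", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Default configuration for the end-to-end synthetic study
#'
#' Three slab devices spanning the low-SPR regime (a cushion, a vacuum
#' bag, and a base-of-skull insert surrogate) with TPS-vs-true SPR errors
#' of roughly -21%, -26% and -35%, and three head-and-neck-like phantom
#' cases immobilized on the cushion with a posterior and a lateral beam, a
#' proximal OAR (cord-like, upstream of the target for the posterior
#' beam) and a distal OAR (oral-cavity-like, downstream).
#'
#' @param seed integer RNG seed controlling every stochastic element.
#' @param output_dir where [run_study()] writes its report bundle.
#' @return A nested configuration list.
#' @export
default_study_config <- function(seed = 1L,
                                 output_dir = file.path(tempdir(), "protonWET-study")) {
  oars <- list(
    list(name = "proximal_oar", center_mm = c(0, -30, 0), radius_mm = 6),
    list(name = "distal_oar", center_mm = c(0, 28, 0), radius_mm = 6)
  )
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    bragg = list(nominal_range_mm = 259, straggling_sigma_mm = 3.1,
                 plateau_entrance_ratio = 0.30, chamber_pitch_mm = 2,
                 n_chambers = 180L),
    measurement = list(noise_cv = 0, n_repeats = 3L),
    devices = list(
      list(name = "cushion", true_rsp = 0.101, tps_rsp = 0.080,
           thickness_mm = 30, n_locations = 3L, location_jitter_cv = 0.03),
      list(name = "vacuum_bag", true_rsp = 0.070, tps_rsp = 0.052,
           thickness_mm = 50, n_locations = 3L, location_jitter_cv = 0.03),
      list(name = "bos_insert_body", true_rsp = 0.189, tps_rsp = 0.122,
           thickness_mm = 33, n_locations = 3L, location_jitter_cv = 0.03)
    ),
    cases = list(
      list(name = "hn01", device = "cushion", ctv_center_mm = c(0, 0, 0)),
      list(name = "hn02", device = "cushion", ctv_center_mm = c(5, 0, 0)),
      list(name = "hn03", device = "cushion", ctv_center_mm = c(0, 5, 0))
    ),
    case_defaults = list(body_radius_mm = 60, ctv_radius_mm = 15,
                         oars = oars, device_thickness_mm = 30,
                         device_gap_mm = 2, device_tps_rsp = 0.080,
                         gantry_angles_deg = c(180, 90),
                         prescription_dose = 100, spacing_mm = 2,
                         z_extent_mm = 40, setup_uncertainty_mm = 3,
                         range_uncertainty_fraction = 0.035),
    evaluate_robustness = TRUE,
    write_grids = TRUE
  )
}

run_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      pw_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               "protonWET_stage_error")
    }),
    message = function(m) invokeRestart("muffleMessage")
  )
}

metrics_row <- function(case, structure, m_without, m_with) {
  metric <- c("v95_pct", "d95_pct", "max_dose_pct", "mean_dose_pct",
              "conformity_index")
  wo <- unlist(m_without[metric])
  wi <- unlist(m_with[metric])
  data.frame(case = case, structure = structure, metric = metric,
             without_override = wo, with_override = wi,
             delta = wi - wo,
             pct_delta = ifelse(wo != 0, 100 * (wi - wo) / wo, NA_real_),
             row.names = NULL)
}

#' Run the full synthetic SPR-error study
#'
#' Executes the complete pipeline: build each synthetic device phantom,
#' measure its SPR by the simulated range-shift method and by the
#' planning-system ray trace, compare the two; then, per patient-like
#' case, compute the plan dose with and without the density override,
#' evaluate nominal and (optionally) worst-case robustness DVH metrics for
#' the target and OARs plus beam-specific coverage, and test the paired
#' before/after metrics with the exact Wilcoxon signed-rank test.  Writes
#' `table1_summary.csv`, `dvh_metrics.csv`, `dvh_curves.csv`,
#' `comparison_report.json`, a `run_log.txt`, and (optionally)
#' per-case dose-difference NRRD grids into the output directory.  The
#' whole run is deterministic given `config$seed`.
#'
#' @param config a configuration list ([default_study_config()]) or a path
#'   to a YAML/JSON file ([read_config()]).
#' @return A list of class `study_report` (invisibly also written to
#'   disk): device comparisons, summary, per-case metric table, Wilcoxon
#'   results, and output paths.
#' @export
run_study <- function(config = default_study_config()) {
  if (is.character(config)) config <- read_config(config)
  pw_check(is.list(config), "`config` must be a list or a file path")
  pw_check(length(config$devices) >= 1, "config must define at least one device")
  pw_check(!is.null(config$seed), "config must set an explicit seed")
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir %||% file.path(tempdir(), "protonWET-study")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log_stage <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  log_stage("protonWET %s | seed %d", as.character(utils::packageVersion("protonWET")), seed)

  curve <- run_stage("calibration", {
    if (!is.null(config$calibration$hu_path)) {
      read_calibration_csv(config$calibration$hu_path,
                           config$calibration$rsp_path)
    } else default_calibration()
  })
  log_stage("stage calibration: %d HU nodes", length(curve$hu))

  model <- run_stage("bragg_model", {
    bragg_model(do.call(bragg_params, c(config$bragg, list(seed = seed))))
  })
  log_stage("stage bragg_model: R80 %.1f mm", model$params$nominal_range_mm)

  noise_cv <- config$measurement$noise_cv %||% 0
  n_rep <- config$measurement$n_repeats %||% 3L
  comparisons <- run_stage("device_measurement", {
    lapply(seq_along(config$devices), function(i) {
      dv <- config$devices[[i]]
      spec <- device_spec(dv$name, dv$true_rsp, dv$thickness_mm,
                          reported_hu = dv$reported_hu, tps_rsp = dv$tps_rsp,
                          n_locations = dv$n_locations %||% 3L,
                          location_jitter_cv = dv$location_jitter_cv %||% 0)
      dev <- generate_device_phantom(spec, curve, seed = seed + i)
      measured <- simulate_device_measurement(dev, model, noise_cv = noise_cv,
                                              seed = seed + 100L * i)
      tps <- measure_device_tps(dev, curve, n_repeats = n_rep)
      compare_spr(tps, measured)
    })
  })
  names(comparisons) <- vapply(comparisons, `[[`, "", "device")
  table1 <- summarize_table1(comparisons)
  utils::write.csv(table1$rows, file.path(out_dir, "table1_summary.csv"),
                   row.names = FALSE)
  log_stage("stage device_measurement: %d devices, mean SPR diff %.1f%%",
            nrow(table1$rows), table1$mean_pct_diff)

  metric_tab <- NULL
  dvh_curves <- NULL
  case_names <- character()
  for (ci in seq_along(config$cases)) {
    cs <- config$cases[[ci]]
    case_args <- utils::modifyList(config$case_defaults %||% list(),
                                   cs[setdiff(names(cs), "device")])
    case <- do.call(case_spec, case_args)
    pp <- run_stage(paste0("phantom_", case$name),
                    generate_patient_phantom(case, curve))
    cmp <- comparisons[[cs$device %||% names(comparisons)[1]]]
    ov <- list(list(record = make_override(cmp$tps_spr, cmp$measured_spr,
                                           device = cmp$device),
                    mask = pp$masks$device))
    rx <- pp$plan$prescription_dose
    res <- run_stage(paste0("dose_", case$name), {
      dose_wo <- compute_dose(pp$phantom, pp$plan, curve)
      dose_wi <- compute_dose(pp$phantom, pp$plan, curve, overrides = ov)
      list(wo = dose_wo, wi = dose_wi)
    })
    eval_masks <- c(list(ctv = pp$masks$ctv),
                    pp$masks[setdiff(names(pp$masks), c("ctv", "body", "device"))])
    if (isTRUE(config$evaluate_robustness)) {
      sc_wo <- run_stage(paste0("scenarios_", case$name),
                         scenario_doses(pp$phantom, pp$plan, curve))
      sc_wi <- run_stage(paste0("scenarios_override_", case$name),
                         scenario_doses(pp$phantom, pp$plan, curve, overrides = ov))
      wc <- function(scns) worst_case_metrics(
        lapply(scns, function(d) dvh_metrics(d, pp$masks$ctv, rx)))
      metric_tab <- rbind(metric_tab,
                          metrics_row(case$name, "ctv_worst_case",
                                      wc(sc_wo), wc(sc_wi)))
    }
    for (nm in names(eval_masks)) {
      with_ci <- nm == "ctv"
      metric_tab <- rbind(metric_tab,
                          metrics_row(case$name, nm,
                                      dvh_metrics(res$wo, eval_masks[[nm]], rx, with_ci),
                                      dvh_metrics(res$wi, eval_masks[[nm]], rx, with_ci)))
    }
    pb_wo <- compute_dose(pp$phantom, pp$plan, curve, per_beam = TRUE)
    pb_wi <- compute_dose(pp$phantom, pp$plan, curve, overrides = ov,
                          per_beam = TRUE)
    bm_wo <- beam_specific_metrics(pb_wo, pp$masks$ctv, rx)
    bm_wi <- beam_specific_metrics(pb_wi, pp$masks$ctv, rx)
    for (b in seq_along(bm_wo)) {
      metric_tab <- rbind(metric_tab,
                          metrics_row(case$name, sprintf("ctv_beam%d", b),
                                      bm_wo[[b]], bm_wi[[b]]))
    }
    crv_wo <- cumulative_dvh(res$wo, pp$masks$ctv, rx, n_bins = 220L)
    crv_wi <- cumulative_dvh(res$wi, pp$masks$ctv, rx, n_bins = 220L)
    dvh_curves <- rbind(dvh_curves,
                        cbind(case = case$name, override = "without", crv_wo),
                        cbind(case = case$name, override = "with", crv_wi))
    if (isTRUE(config$write_grids)) {
      diff_grid <- res$wi
      diff_grid$values <- res$wi$values - res$wo$values
      write_nrrd(diff_grid, file.path(out_dir,
                                      sprintf("dose_diff_%s.nrrd", case$name)))
    }
    case_names <- c(case_names, case$name)
    log_stage("stage case %s: %d beams, %d structures evaluated",
              case$name, length(pp$plan$beams), length(eval_masks))
  }
  utils::write.csv(metric_tab, file.path(out_dir, "dvh_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(dvh_curves, file.path(out_dir, "dvh_curves.csv"),
                   row.names = FALSE)

  wilcox_tab <- NULL
  if (length(case_names) >= 1 && !is.null(metric_tab)) {
    for (str in unique(metric_tab$structure)) {
      for (met in unique(metric_tab$metric)) {
        sub <- metric_tab[metric_tab$structure == str & metric_tab$metric == met, ]
        if (nrow(sub) < 1 || anyNA(sub$delta) || all(sub$delta == 0)) next
        wt <- wilcoxon_signed_rank(sub$delta)
        wilcox_tab <- rbind(wilcox_tab,
                            data.frame(structure = str, metric = met,
                                       n = wt$n, W = wt$statistic,
                                       p_value = wt$p.value,
                                       significant = wt$p.value < 0.05))
      }
    }
  }
  report <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("protonWET")),
    table1 = list(rows = table1$rows,
                  mean_pct_diff = table1$mean_pct_diff,
                  min_pct_diff = table1$min_pct_diff,
                  max_pct_diff = table1$max_pct_diff,
                  max_abs_wet_diff_mm = table1$max_abs_wet_diff_mm),
    wilcoxon = wilcox_tab,
    cases = case_names,
    log = log_lines
  )
  jsonlite::write_json(report, file.path(out_dir, "comparison_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(structure(list(comparisons = comparisons, table1 = table1,
                           metrics = metric_tab, wilcoxon = wilcox_tab,
                           output_dir = out_dir, log = log_lines),
                      class = "study_report"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_report <- function(x, ...) {
  cat("protonWET synthetic study report\n")
  print(x$table1)
  if (!is.null(x$wilcoxon)) {
    cat("\nWilcoxon signed-rank (override vs no override):\n")
    print(x$wilcoxon, row.names = FALSE)
  }
  cat(sprintf("\noutputs in %s\n", x$output_dir))
  invisible(x)
}
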