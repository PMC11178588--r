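#' @title Study workflow: calibration to report
#' @description
#' Orchestrates the full analysis of a study: per-window phantom calibration,
#' activity quantification and SUV extraction at both time points, lesion
#' isocontour segmentation on the filtered 24-h image (reused at 48 h),
#' mono-exponential TAC fitting, RBE-weighted self-dosimetry under the three
#' chain-partitioning methods, urine Bateman fitting with cohort ratio
#' summaries, and the cohort statistics. The 78-keV window participates in
#' the SUV and half-life reports but is excluded from dosimetry. Given the
#' same configuration the run is fully deterministic and the emitted CSVs are
#' byte-identical.
#' @name workflow
NULL

#' Build a study configuration
#'
#' @param scenario a [cohort_scenario()]; the synthetic inputs are generated
#'   from it on the fly.
#' @param out_dir directory for the report CSVs and run log (optional; when
#'   `NULL` nothing is written and the tables are only returned).
#' @param filter_fwhm_mm Gaussian post-filter FWHM, mm (default 30).
#' @param isocontour_fraction lesion isocontour threshold (default 0.8).
#' @param rbe RBE multiplier for the weighted doses (default 5).
#' @param integrate_from_h lower bound of the dose integral, hours.
#' @param report_windows windows included in the SUV/half-life reports.
#' @param dose_windows windows feeding dosimetry (default Bi-213 and Fr-221).
#' @param statistics_on_filtered read SUV statistics from the filtered image
#'   (default) or from the unfiltered calibrated image.
#' @return a `study_config`.
#' @export
study_config <- function(scenario, out_dir = NULL, filter_fwhm_mm = 30,
                         isocontour_fraction = 0.8, rbe = 5,
                         integrate_from_h = 0,
                         report_windows = c("bi440", "fr218", "xr78"),
                         dose_windows = c("bi440", "fr218"),
                         statistics_on_filtered = TRUE) {
  if (!inherits(scenario, "cohort_scenario")) {
    abort_acdosim("scenario must be a cohort_scenario", "acdosim_configuration_error")
  }
  structure(list(scenario = scenario, out_dir = out_dir,
                 filter_fwhm_mm = filter_fwhm_mm,
                 isocontour_fraction = isocontour_fraction, rbe = rbe,
                 integrate_from_h = integrate_from_h,
                 report_windows = report_windows, dose_windows = dose_windows,
                 statistics_on_filtered = statistics_on_filtered),
            class = "study_config")
}

#' Read a study configuration from JSON
#'
#' The JSON mirrors the [study_config()] / [cohort_scenario()] arguments:
#' top-level analysis switches plus a `scenario` object whose fields are
#' passed to `cohort_scenario()`.
#'
#' @param path JSON file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc_args <- js$scenario %||% list()
  for (nm in c("kidney_teff_h", "lesion_teff_h", "kidney_suv24", "lesion_suv24",
               "calibration_factors", "urine_ratio24", "urine_ratio48")) {
    if (!is.null(sc_args[[nm]])) sc_args[[nm]] <- unlist(sc_args[[nm]])
  }
  scenario <- do.call(cohort_scenario, sc_args)
  cfg_args <- js[setdiff(names(js), "scenario")]
  do.call(study_config, c(list(scenario = scenario), cfg_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bounding box of a truth mask, expanded by `margin` voxels: the lesion
# search region handed to the isocontour segmentation
.search_region <- function(truth, margin = 3L) {
  dims <- dim(truth$mask)
  idx <- arrayInd(which(truth$mask), dims)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dims)
  m <- array(FALSE, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  voi_mask(m, label = truth$label, origin = "search_region")
}

#' Run the full pipeline
#'
#' @param config a [study_config()] (or a bare `cohort_scenario`, in which
#'   case default switches apply).
#' @return (invisibly when writing files) a list of report tables:
#'   `calibration`, `suv`, `halflife`, `dose`, `dose_diff`, `urine`,
#'   `urine_summary`, `stats`, `rejected_tacs`, and `log` (the settings in
#'   force). With `out_dir` set, writes one CSV per table plus
#'   `run_log.json`.
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "cohort_scenario")) config <- study_config(config)
  sc <- config$scenario
  windows <- config$report_windows

  ## 1. calibration per window
  calib <- list(); cal_rows <- list()
  for (w in windows) {
    ph <- make_calibration_phantom(sc, window = w,
                                   matrix_size = max(sc$matrix_size, 80L))
    f <- compute_calibration_factor(ph$image, ph$truth_concentration_bqml,
                                    ph$central_voi,
                                    provenance = "uniform cylinder phantom")
    calib[[w]] <- f
    cal_rows[[w]] <- data.frame(window = w, window_kev = f$window_kev,
                                factor_cps_per_bqml = f$value,
                                truth_factor = sc$calibration_factors[[w]])
  }
  calibration <- do.call(rbind, cal_rows); rownames(calibration) <- NULL

  ## 2. quantification and SUV per patient / time / window
  suv_rows <- list(); fit_rows <- list(); rejected <- list()
  dose_rows <- list(); diff_rows <- list()
  for (pid in names(sc$patients)) {
    pat <- sc$patients[[pid]]
    per_voi <- list()   # [[voi]][[window]] -> list(act24, act48, vol24, suv per time)
    for (w in windows) {
      lesion_masks <- list()
      for (time_h in sc$time_points_h) {
        sim <- make_phantom_image(sc, pid, time_h, w)
        img <- apply_calibration(sim$image, calib[[w]])
        filt <- gaussian_postfilter(img, config$filter_fwhm_mm)
        stat_img <- if (config$statistics_on_filtered) filt else img
        for (org in pat$organs) {
          if (org$is_lesion) {
            if (time_h == sc$time_points_h[1]) {
              # segment on the filtered 24-h image, separately per window
              mask <- isocontour_mask(filt, .search_region(sim$truth_masks[[org$label]]),
                                      fraction = config$isocontour_fraction,
                                      label = org$label)
              lesion_masks[[org$label]] <- mask
            }
            mask <- lesion_masks[[org$label]]
          } else {
            mask <- sim$truth_masks[[org$label]]  # CT-based, supplied
          }
          q <- voi_quant(stat_img, mask, pat$injected_mbq, pat$weight_kg)
          suv_rows[[length(suv_rows) + 1L]] <- data.frame(
            patient = pid, voi = org$label, is_lesion = org$is_lesion,
            window = w, window_kev = sc$windows$kev[sc$windows$window == w],
            time_h = time_h, suv_mean = q$suv_mean,
            conc_mean_bqml = q$mean_concentration_bqml,
            volume_ml = q$volume_ml, total_activity_bq = q$total_activity_bq)
          key <- org$label
          if (is.null(per_voi[[key]])) per_voi[[key]] <- list()
          per_voi[[key]][[w]][[as.character(time_h)]] <- q
        }
      }
    }

    ## 3. TAC fits per VOI and window
    fits <- list()
    for (voi in names(per_voi)) {
      for (w in windows) {
        qs <- per_voi[[voi]][[w]]
        acts <- vapply(as.character(sc$time_points_h),
                       function(k) qs[[k]]$total_activity_bq, 0)
        fit <- tryCatch(fit_monoexp(sc$time_points_h, acts),
                        acdosim_non_decaying_tac = function(e) e)
        if (inherits(fit, "condition")) {
          rejected[[length(rejected) + 1L]] <- data.frame(
            patient = pid, voi = voi, window = w, reason = conditionMessage(fit))
          next
        }
        fits[[voi]][[w]] <- fit
        t_bio <- if (fit$t_eff_h < chain_nuclide("Ac-225")$half_life_h) {
          biological_half_life(fit$t_eff_h, "Ac-225")$t_bio_h
        } else NA_real_
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          patient = pid, voi = voi,
          is_lesion = pat$organs[[voi]]$is_lesion, window = w,
          window_kev = sc$windows$kev[sc$windows$window == w],
          a_t0_bq = fit$a_t0_bq, t_eff_h = fit$t_eff_h, t_bio_h = t_bio)
      }
    }

    ## 4. dosimetry (Bi-213 and Fr-221 windows only)
    cfg_dose <- dose_config(rbe = config$rbe,
                            integrate_from_h = config$integrate_from_h)
    for (voi in names(per_voi)) {
      bi <- fits[[voi]][["bi440"]]; fr <- fits[[voi]][["fr218"]]
      if (is.null(bi) || is.null(fr)) next
      # VOI mass: 24-h segmented volume of the Bi-213 window, density 1 g/ml
      mass_g <- per_voi[[voi]][["bi440"]][["24"]]$volume_ml
      d1 <- dose_method1(bi, mass_g, cfg_dose, pat$injected_mbq)
      d2 <- dose_method2(fr, mass_g, cfg_dose, pat$injected_mbq)
      d3 <- dose_method3(fr, bi, mass_g, cfg_dose, pat$injected_mbq)
      for (d in list(d1, d2, d3)) {
        dose_rows[[length(dose_rows) + 1L]] <- data.frame(
          patient = pid, voi = voi, is_lesion = pat$organs[[voi]]$is_lesion,
          method = d$method, mass_g = mass_g, absorbed_gy = d$absorbed_gy,
          sv_rbe = d$sv_rbe, sv_rbe_per_mbq = d$sv_rbe_per_mbq)
      }
      for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
        ds <- list(d1, d2, d3)
        diff_rows[[length(diff_rows) + 1L]] <- data.frame(
          patient = pid, voi = voi, is_lesion = pat$organs[[voi]]$is_lesion,
          comparison = sprintf("method%d_vs_method%d", pair[1], pair[2]),
          pct_diff_symmetric = method_percent_difference(ds[[pair[1]]], ds[[pair[2]]]),
          pct_diff_relative = method_percent_difference(ds[[pair[1]]], ds[[pair[2]]],
                                                        "relative_b"))
      }
    }
  }
  suv <- do.call(rbind, suv_rows); rownames(suv) <- NULL
  halflife <- do.call(rbind, fit_rows); rownames(halflife) <- NULL
  dose <- if (length(dose_rows)) do.call(rbind, dose_rows) else NULL
  dose_diff <- if (length(diff_rows)) do.call(rbind, diff_rows) else NULL
  rejected_tacs <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(patient = character(0), voi = character(0),
               window = character(0), reason = character(0))

  ## 5. urine analysis
  urine_rows <- list()
  for (pid in names(sc$patients)) {
    pat <- sc$patients[[pid]]
    for (ep in names(pat$urine)) {
      tru <- pat$urine[[ep]]
      pidx <- match(pid, names(sc$patients))
      series <- simulate_urine_series(
        tru$a_ac0_bqml, tru$a_bi0_bqml,
        efficiency = sc$urine$efficiency, dt_h = sc$urine$dt_h,
        duration_h = sc$urine$duration_h,
        seed = sc$seed * 883 + pidx * 10 + match(ep, names(pat$urine)),
        collection_time_h = tru$collection_time_h,
        sample_id = paste0(pid, "_", ep))
      fit <- fit_urine_series(series)
      urine_rows[[length(urine_rows) + 1L]] <- data.frame(
        patient = pid, epoch = ep,
        collection_time_h = tru$collection_time_h,
        ac_bqml = fit$a_ac0_bq, bi_bqml = fit$a_bi0_bq,
        ratio = bi_ac_ratio_at(fit),
        arbitrary_scale = fit$arbitrary_scale)
    }
  }
  urine <- do.call(rbind, urine_rows); rownames(urine) <- NULL
  usum <- cohort_ratio_summary(urine$patient, urine$epoch, urine$ratio)
  urine_summary <- data.frame(
    epoch = c(usum$epochs, "change"),
    mean = c(usum$epoch_mean, usum$mean_change_points),
    sd = c(usum$epoch_sd, usum$sd_change_points),
    unit = c("ratio", "ratio", "percentage_points"))

  ## 6. cohort statistics
  stats_rows <- list()
  add_stat <- function(comparison, n, statistic, p, method) {
    stats_rows[[length(stats_rows) + 1L]] <<- data.frame(
      comparison = comparison, n = n, statistic = statistic,
      p_two_sided = p, method = method)
  }
  for (time_h in sc$time_points_h) {
    for (lesion in c(FALSE, TRUE)) {
      a <- suv[suv$window == "bi440" & suv$time_h == time_h & suv$is_lesion == lesion, ]
      b <- suv[suv$window == "fr218" & suv$time_h == time_h & suv$is_lesion == lesion, ]
      m <- merge(a, b, by = c("patient", "voi"))
      if (nrow(m) >= 3) {
        pt <- pearson_test(m$suv_mean.x, m$suv_mean.y)
        add_stat(sprintf("suv_bi_vs_fr_%s_%dh", if (lesion) "lesions" else "kidneys",
                         time_h),
                 pt$n, pt$r, pt$p_value, "pearson")
      }
    }
  }
  for (lesion in c(FALSE, TRUE)) {
    a <- halflife[halflife$window == "bi440" & halflife$is_lesion == lesion, ]
    b <- halflife[halflife$window == "fr218" & halflife$is_lesion == lesion, ]
    m <- merge(a, b, by = c("patient", "voi"))
    if (nrow(m) >= 2) {
      pt <- if (nrow(m) >= 3) {
        tryCatch(pearson_test(m$t_eff_h.x, m$t_eff_h.y),
                 acdosim_degenerate_input = function(e) NULL)
      }
      if (!is.null(pt)) {
        add_stat(sprintf("teff_bi_vs_fr_%s_correlation",
                         if (lesion) "lesions" else "kidneys"),
                 pt$n, pt$r, pt$p_value, "pearson")
      }
      wt <- tryCatch(wilcoxon_signed_rank(m$t_eff_h.x, m$t_eff_h.y),
                     acdosim_degenerate_input = function(e) NULL)
      if (!is.null(wt)) {
        add_stat(sprintf("teff_bi_vs_fr_%s_wilcoxon",
                         if (lesion) "lesions" else "kidneys"),
                 wt$n_used, wt$statistic, wt$p_value,
                 paste0("wilcoxon_", wt$method))
      }
    }
  }
  if (!is.null(dose)) {
    d3 <- dose[dose$method == 3L, ]
    d3$value <- d3$sv_rbe_per_mbq
    pairs <- tryCatch(kidney_lesion_pairs(d3), acdosim_pairing_error = function(e) NULL)
    if (!is.null(pairs) && nrow(pairs) >= 2) {
      wt <- wilcoxon_signed_rank(pairs$lesion_value, pairs$kidney_value)
      add_stat("dose_lesion_vs_kidney_wilcoxon", wt$n_used, wt$statistic,
               wt$p_value, paste0("wilcoxon_", wt$method))
    }
  }
  stats_tab <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL

  log <- list(
    package_version = as.character(utils::packageVersion("acdosim")),
    seed = sc$seed, n_patients = sc$n_patients,
    matrix_size = sc$matrix_size, voxel_mm = sc$voxel_mm,
    noise = sc$noise, psf_fwhm_mm = sc$psf_fwhm_mm,
    filter_fwhm_mm = config$filter_fwhm_mm,
    isocontour_fraction = config$isocontour_fraction,
    statistics_on_filtered = config$statistics_on_filtered,
    rbe = config$rbe, integrate_from_h = config$integrate_from_h,
    dose_windows = config$dose_windows,
    sd_convention = "population",
    percent_difference_convention = "symmetric (relative also reported)",
    n_rejected_tacs = nrow(rejected_tacs))

  out <- list(calibration = calibration, suv = suv, halflife = halflife,
              dose = dose, dose_diff = dose_diff, urine = urine,
              urine_summary = urine_summary, stats = stats_tab,
              rejected_tacs = rejected_tacs, log = log)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(out), "log")) {
      if (!is.null(out[[nm]])) {
        utils::write.csv(out[[nm]], file.path(config$out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
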