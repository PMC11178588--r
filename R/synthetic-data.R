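#' @title Seeded synthetic-data generators
#' @description
#' Generators for every input the pipeline consumes: voxel phantoms with
#' organ kinetics, system blur and Poisson counting noise; two-point VOI
#' time-activity tables with multiplicative lognormal noise; and urine
#' gamma-counter series with Poisson counts per bin. All stochastic draws
#' derive from the scenario seed through per-component sub-streams, so the
#' generators are pure functions of (scenario, seed) and changing one
#' generator does not shift another's draws.
#'
#' The default scenario mirrors a five-patient [225Ac]Ac-PSMA therapy cohort:
#' injected activities 7.9/8.0/7.8/7.6/7.4 MBq, two SPECT time points (24 and
#' 48 h p.i.), three energy windows (440 keV/20% for Bi-213, 218 keV/20% for
#' Fr-221, 78 keV/50% for X-rays), eight analyzed kidneys plus nine lesions,
#' kidney effective half-lives around 27/24/23 h and lesion half-lives around
#' 38 h, kidney volumes ~247 ml and lesion volumes ~23 ml, and urine Bi/Ac
#' ratios drawn around 0.98 at ~24 h and 1.08 at ~48 h.
#' @name synthetic_data
NULL

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.WINDOWS <- data.frame(
  window = c("bi440", "fr218", "xr78"),
  kev = c(440, 218, 78),
  width_pct = c(20, 20, 50),
  surrogate = c("Bi-213", "Fr-221", "X-rays"),
  stringsAsFactors = FALSE)

# lognormal factor with median 1 and the stated coefficient of variation
.lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

#' Build a cohort scenario
#'
#' Fixes every ground truth of a synthetic study: patient demographics,
#' per-organ amplitudes and effective half-lives per energy window, organ
#' geometry on the voxel grid, urine amplitudes per collection epoch, and the
#' noise model. Per-patient and per-organ variation is drawn once here
#' (seeded), so the scenario object itself is the complete ground truth.
#'
#' @param seed master seed; every stochastic draw in the scenario and in the
#'   generators derives from it.
#' @param n_patients number of patients (defaults taken from the first
#'   `n_patients` entries of the cohort vectors).
#' @param injected_mbq,weight_kg per-patient injected activity and weight.
#' @param n_lesions lesions per patient in the imaged field of view.
#' @param matrix_size,voxel_mm image grid (isotropic voxels).
#' @param kidney_teff_h,lesion_teff_h named per-window mean effective
#'   half-lives, hours.
#' @param kidney_suv24,lesion_suv24 named per-window mean SUVs at 24 h.
#' @param kidney_volume_ml,lesion_volume_ml mean segmented volumes.
#' @param teff_cv,suv_cv,volume_cv between-subject coefficients of variation.
#' @param background_suv24 uniform body-background SUV at 24 h.
#' @param psf_fwhm_mm isotropic system resolution applied by the image
#'   generator (0 disables blur).
#' @param count_time_s effective counting time per voxel for the Poisson
#'   noise model; `noise = "none"` disables noise.
#' @param calibration_factors named (cps/voxel)/(Bq/ml) truth per window.
#' @param noise `"poisson"` or `"none"`.
#' @param urine_ac24_bqml,urine_ac48_bqml per-patient Ac-225 urine
#'   concentrations at the two collection epochs.
#' @param urine_ratio24,urine_ratio48 mean and SD (length-2 vectors) of the
#'   Bi/Ac ratio truth at each epoch.
#' @param urine_collection24_h,urine_collection48_h collection times, hours
#'   post-injection.
#' @param urine_efficiency,urine_dt_h,urine_duration_h counter efficiency
#'   (counts per decay), bin width and measurement duration.
#' @param tac_cv multiplicative noise CV for tabulated TACs.
#' @return a `cohort_scenario` list.
#' @export
cohort_scenario <- function(seed = 1L,
                            n_patients = 5L,
                            injected_mbq = c(7.9, 8.0, 7.8, 7.6, 7.4),
                            weight_kg = c(107, 85, 70, 93, 98),
                            n_lesions = c(0L, 2L, 3L, 2L, 2L),
                            matrix_size = 128L,
                            voxel_mm = 4.7952,
                            kidney_teff_h = c(bi440 = 27, fr218 = 24, xr78 = 23),
                            lesion_teff_h = c(bi440 = 38, fr218 = 38, xr78 = 39),
                            kidney_suv24 = c(bi440 = 3.4, fr218 = 3.2, xr78 = 4.3),
                            lesion_suv24 = c(bi440 = 5.3, fr218 = 4.8, xr78 = 5.8),
                            kidney_volume_ml = 247,
                            lesion_volume_ml = 23,
                            teff_cv = 0.2,
                            suv_cv = 0.2,
                            volume_cv = 0.25,
                            background_suv24 = 0.2,
                            psf_fwhm_mm = 15,
                            count_time_s = 3360,
                            calibration_factors = c(bi440 = 1e-4, fr218 = 1.5e-4,
                                                    xr78 = 3e-4),
                            noise = c("poisson", "none"),
                            urine_ac24_bqml = c(242.6, 232.9, 61.1, 303.9, 128.6),
                            urine_ac48_bqml = c(38.7, 38.8, 44.1, 42.9, 113.2),
                            urine_ratio24 = c(mean = 0.98, sd = 0.15),
                            urine_ratio48 = c(mean = 1.08, sd = 0.09),
                            urine_collection24_h = c(17.0, 18.0, 22.0, 17.0, 18.6),
                            urine_collection48_h = c(42.5, 41.3, 39.0, 40.6, 42.0),
                            urine_efficiency = 0.25,
                            urine_dt_h = 0.25,
                            urine_duration_h = 8,
                            tac_cv = 0.1) {
  noise <- match.arg(noise)
  n <- n_patients
  take <- function(x) rep_len(x, n)
  injected_mbq <- take(injected_mbq); weight_kg <- take(weight_kg)
  n_lesions <- take(n_lesions)
  urine_ac24_bqml <- take(urine_ac24_bqml); urine_ac48_bqml <- take(urine_ac48_bqml)
  urine_collection24_h <- take(urine_collection24_h)
  urine_collection48_h <- take(urine_collection48_h)
  fov_mm <- matrix_size * voxel_mm
  windows <- .WINDOWS$window

  patients <- with_seed(derive_seed(seed, "cohort"), {
    lapply(seq_len(n), function(p) {
      organs <- list()
      # kidneys: a patient-level kinetic factor keeps the per-window ordering
      # (Fr-221 below Bi-213) while varying between subjects
      kid_factor <- .lnorm_factor(1, teff_cv)
      kid_a <- c(left = NA_real_, right = NA_real_)
      for (side in c("left", "right")) {
        side_jit <- .lnorm_factor(1, teff_cv / 3)
        uptake <- .lnorm_factor(1, suv_cv)
        vol <- kidney_volume_ml * .lnorm_factor(1, volume_cv)
        a <- (3 * vol * 1000 / (4 * pi * 2.2))^(1 / 3)
        kid_a[side] <- a
        # abut the kidneys left/right of the midline with an 8-mm gap,
        # so the layout fits any grid large enough for the organs
        xc <- (a + 8) * if (side == "left") -1 else 1
        organs[[paste0("kidney_", side)]] <- list(
          label = paste0("kidney_", side), is_lesion = FALSE,
          center_mm = c(xc, 8, 0),
          semiaxes_mm = c(a, a, 2.2 * a),
          volume_ml = vol,
          teff_h = kidney_teff_h * kid_factor * side_jit,
          suv24 = kidney_suv24 * uptake * .lnorm_factor(3, suv_cv / 4))
      }
      if (n_lesions[p] > 0) {
        vols <- lesion_volume_ml * .lnorm_factor(n_lesions[p], volume_cv)
        radii <- (3 * vols * 1000 / (4 * pi))^(1 / 3)
        # 30-mm surface gap keeps each lesion's segmentation search region
        # clear of its neighbours
        spacing <- 2 * max(radii) + 30
        y_les <- 8 - max(kid_a) - max(radii) - 12  # anterior to both kidneys
        for (k in seq_len(n_lesions[p])) {
          uptake <- .lnorm_factor(1, suv_cv)
          organs[[paste0("lesion_", k)]] <- list(
            label = paste0("lesion_", k), is_lesion = TRUE,
            center_mm = c((k - (n_lesions[p] + 1) / 2) * spacing, y_les, 0),
            semiaxes_mm = rep(radii[k], 3),
            volume_ml = vols[k],
            # lesion kinetics: a lesion-level factor plus small per-window
            # jitter (the windows agree on average but not exactly)
            teff_h = lesion_teff_h * .lnorm_factor(1, teff_cv) *
              .lnorm_factor(3, teff_cv / 6),
            suv24 = lesion_suv24 * uptake * .lnorm_factor(3, suv_cv / 4))
        }
      }
      ratio24 <- max(stats::rnorm(1, urine_ratio24[["mean"]], urine_ratio24[["sd"]]), 0.1)
      ratio48 <- max(stats::rnorm(1, urine_ratio48[["mean"]], urine_ratio48[["sd"]]), 0.1)
      list(id = paste0("patient_", p),
           injected_mbq = injected_mbq[p], weight_kg = weight_kg[p],
           organs = organs,
           urine = list(
             `24h` = list(collection_time_h = urine_collection24_h[p],
                          a_ac0_bqml = urine_ac24_bqml[p],
                          a_bi0_bqml = urine_ac24_bqml[p] * ratio24),
             `48h` = list(collection_time_h = urine_collection48_h[p],
                          a_ac0_bqml = urine_ac48_bqml[p],
                          a_bi0_bqml = urine_ac48_bqml[p] * ratio48)))
    })
  })
  names(patients) <- vapply(patients, `[[`, "", "id")

  sc <- structure(list(
    seed = seed, n_patients = n, patients = patients,
    matrix_size = matrix_size, voxel_mm = voxel_mm,
    windows = .WINDOWS,
    background_suv24 = background_suv24,
    background_teff_h = kidney_teff_h,
    psf_fwhm_mm = psf_fwhm_mm, count_time_s = count_time_s,
    calibration_factors = calibration_factors, noise = noise,
    phantom = list(concentration_bqml = 524, diameter_mm = 255,
                   volume_l = 8.7),
    urine = list(efficiency = urine_efficiency, dt_h = urine_dt_h,
                 duration_h = urine_duration_h),
    tac_cv = tac_cv,
    time_points_h = c(24, 48)
  ), class = "cohort_scenario")
  .check_geometry(sc)
  sc
}

.voxel_centers_mm <- function(n, voxel) (seq_len(n) - (n + 1) / 2) * voxel

.organ_mask <- function(organ, dims, voxel) {
  x <- .voxel_centers_mm(dims[1], voxel)
  y <- .voxel_centers_mm(dims[2], voxel)
  z <- .voxel_centers_mm(dims[3], voxel)
  cx <- organ$center_mm; ax <- organ$semiaxes_mm
  u2 <- ((x - cx[1]) / ax[1])^2
  v2 <- ((y - cx[2]) / ax[2])^2
  w2 <- ((z - cx[3]) / ax[3])^2
  arr <- outer(outer(u2, v2, `+`), w2, `+`)
  arr <= 1
}

.check_geometry <- function(sc) {
  dims <- rep(sc$matrix_size, 3L)
  half_fov <- sc$matrix_size * sc$voxel_mm / 2
  for (pat in sc$patients) {
    acc <- array(0L, dims)
    for (org in pat$organs) {
      if (any(abs(org$center_mm) + org$semiaxes_mm > half_fov)) {
        abort_acdosim(sprintf("%s/%s extends beyond the field of view; increase matrix_size",
                              pat$id, org$label),
                      "acdosim_geometry_error")
      }
      m <- .organ_mask(org, dims, sc$voxel_mm)
      if (!any(m)) {
        abort_acdosim(sprintf("%s/%s has no voxels on this grid", pat$id, org$label),
                      "acdosim_geometry_error")
      }
      acc <- acc + m
    }
    if (any(acc > 1L)) {
      abort_acdosim(sprintf("overlapping organs for %s", pat$id),
                    "acdosim_geometry_error")
    }
  }
  invisible(sc)
}

.suv_to_bqml <- function(suv, injected_mbq, weight_kg) {
  suv * injected_mbq * 1e6 / (weight_kg * 1000)
}

#' Simulate one patient SPECT acquisition
#'
#' Paints the patient's organs (concentration decayed from the 24-h truth by
#' each organ's window-specific effective half-life) over a uniform body
#' background, applies the isotropic system blur, converts to cps/voxel with
#' the window's true calibration factor, and adds Poisson counting noise.
#'
#' @param scenario a `cohort_scenario`.
#' @param patient patient index or id.
#' @param time_h acquisition time post-injection, hours.
#' @param window window id (`"bi440"`, `"fr218"`, `"xr78"`).
#' @return list with `image` (`quant_image`, cps/voxel), `truth_masks`
#'   (named `voi_mask` list), `truth_conc_bqml` and `truth_activity_bq`
#'   (named, per organ).
#' @export
make_phantom_image <- function(scenario, patient, time_h, window = "bi440") {
  pat <- if (is.character(patient)) scenario$patients[[patient]] else
    scenario$patients[[patient]]
  if (is.null(pat)) abort_acdosim("unknown patient", "acdosim_invalid_input")
  if (!window %in% scenario$windows$window) {
    abort_acdosim("unknown energy window", "acdosim_configuration_error")
  }
  dims <- rep(scenario$matrix_size, 3L)
  voxel <- scenario$voxel_mm
  conc <- array(.suv_to_bqml(scenario$background_suv24, pat$injected_mbq,
                             pat$weight_kg) *
                  2^(-(time_h - 24) / scenario$background_teff_h[[window]]),
                dims)
  masks <- list(); truth_conc <- c(); truth_act <- c()
  voxel_ml <- voxel^3 / 1000
  for (org in pat$organs) {
    m <- .organ_mask(org, dims, voxel)
    c24 <- .suv_to_bqml(org$suv24[[window]], pat$injected_mbq, pat$weight_kg)
    ct <- c24 * 2^(-(time_h - 24) / org$teff_h[[window]])
    conc[m] <- ct
    masks[[org$label]] <- voi_mask(m, label = org$label, origin = "truth")
    truth_conc[org$label] <- ct
    truth_act[org$label] <- ct * sum(m) * voxel_ml
  }
  img <- quant_image(conc, rep(voxel, 3L), units = "Bq/ml", time_h = time_h,
                     window_kev = scenario$windows$kev[scenario$windows$window == window],
                     window_pct = scenario$windows$width_pct[scenario$windows$window == window])
  if (scenario$psf_fwhm_mm > 0) img <- gaussian_postfilter(img, scenario$psf_fwhm_mm)
  cf <- scenario$calibration_factors[[window]]
  cps <- img$voxels * cf
  if (scenario$noise == "poisson") {
    widx <- match(window, scenario$windows$window)
    pidx <- match(pat$id, names(scenario$patients))
    sub <- derive_seed(scenario$seed * 997 + pidx * 101 + round(time_h) * 7 + widx,
                       "image")
    cps <- with_seed(sub, {
      array(stats::rpois(length(cps), pmax(cps, 0) * scenario$count_time_s),
            dims) / scenario$count_time_s
    })
  }
  img$voxels <- cps
  img$units <- "cps/voxel"
  list(image = img, truth_masks = masks, truth_conc_bqml = truth_conc,
       truth_activity_bq = truth_act)
}

#' Simulate the uniform calibration-phantom acquisition
#'
#' A homogeneously filled cylinder (defaults: 524 Bq/ml, diameter 25.5 cm,
#' 8.7 l, hence 4.56 MBq total) imaged with the window's true calibration
#' factor and Poisson noise. Returns the cps image, the full cylinder truth
#' mask and a central VOI (eroded cylinder) for factor extraction.
#'
#' @param scenario a `cohort_scenario` (uses its phantom description, noise
#'   model and calibration truth).
#' @param window window id.
#' @param matrix_size optional grid override; the 25.5-cm cylinder needs a
#'   field of view of at least ~30 cm.
#' @return list `image`, `cylinder_mask`, `central_voi`,
#'   `truth_concentration_bqml`, `nominal_volume_ml`, `truth_factor`.
#' @export
make_calibration_phantom <- function(scenario, window = "bi440",
                                     matrix_size = NULL) {
  ph <- scenario$phantom
  n <- if (is.null(matrix_size)) scenario$matrix_size else matrix_size
  voxel <- scenario$voxel_mm
  fov <- n * voxel
  r <- ph$diameter_mm / 2
  height <- ph$volume_l * 1e6 / (pi * r^2)
  if (2 * r > 0.95 * fov || height > 0.95 * fov) {
    abort_acdosim("phantom does not fit the field of view; increase matrix_size",
                  "acdosim_geometry_error")
  }
  x <- .voxel_centers_mm(n, voxel); z <- x
  rad2 <- outer(x^2, x^2, `+`)
  cyl <- outer(rad2 <= r^2, abs(z) <= height / 2, `&`)
  conc <- array(0, rep(n, 3L)); conc[cyl] <- ph$concentration_bqml
  img <- quant_image(conc, rep(voxel, 3L), units = "Bq/ml",
                     window_kev = scenario$windows$kev[scenario$windows$window == window])
  if (scenario$psf_fwhm_mm > 0) img <- gaussian_postfilter(img, scenario$psf_fwhm_mm)
  cf <- scenario$calibration_factors[[window]]
  cps <- img$voxels * cf
  if (scenario$noise == "poisson") {
    widx <- match(window, scenario$windows$window)
    cps <- with_seed(derive_seed(scenario$seed * 991 + widx, "calibration"), {
      array(stats::rpois(length(cps), pmax(cps, 0) * scenario$count_time_s),
            rep(n, 3L)) / scenario$count_time_s
    })
  }
  img$voxels <- cps
  img$units <- "cps/voxel"
  margin <- max(scenario$psf_fwhm_mm * 1.5, 20)
  central <- outer(rad2 <= (r - margin)^2, abs(z) <= height / 2 - margin, `&`)
  list(image = img,
       cylinder_mask = voi_mask(cyl, label = "cylinder", origin = "truth"),
       central_voi = voi_mask(central, label = "phantom_voi", origin = "truth"),
       truth_concentration_bqml = ph$concentration_bqml,
       nominal_volume_ml = ph$volume_l * 1000,
       truth_factor = cf)
}

#' Simulate a tabulated VOI time-activity curve
#'
#' Mono-exponential truth with multiplicative lognormal noise of the stated
#' coefficient of variation (median-1 noise factors, so the two-point
#' half-life estimator stays median-unbiased).
#'
#' @param a_t0_bq amplitude at t = 0, Bq.
#' @param t_eff_h effective half-life, hours.
#' @param times_h acquisition times (default the two-scan protocol, 24/48 h).
#' @param cv noise coefficient of variation (0 gives exact values).
#' @param seed seed for the draw.
#' @return data.frame `time_h`, `activity_bq`.
#' @export
simulate_voi_tac <- function(a_t0_bq, t_eff_h, times_h = c(24, 48), cv = 0.1,
                             seed = 1L) {
  if (cv < 0) abort_acdosim("cv must be >= 0", "acdosim_invalid_input")
  truth <- a_t0_bq * 2^(-times_h / t_eff_h)
  noisy <- with_seed(derive_seed(seed, "tac"),
                     truth * .lnorm_factor(length(truth), cv))
  data.frame(time_h = times_h, activity_bq = noisy)
}

#' Simulate a urine gamma-counter series
#'
#' Expected counts per bin are `efficiency` times the number of Bi-213 decays
#' in the bin (exact integral of the Bateman forward model); counts are
#' Poisson draws. With `efficiency = Inf` the series is returned noise-free
#' as instantaneous activities in Bq (the infinite-statistics limit).
#'
#' @param a_ac0_bq,a_bi0_bq Ac-225 and Bi-213 activities at collection, Bq.
#' @param efficiency counts per decay detected in the window; `Inf` for the
#'   noise-free mode.
#' @param dt_h bin width, hours.
#' @param duration_h total measurement duration, hours (>= dt_h).
#' @param seed seed for the Poisson draws.
#' @param collection_time_h,sample_id metadata passed through.
#' @param chain a `decay_chain`.
#' @return a `counting_series`.
#' @export
simulate_urine_series <- function(a_ac0_bq, a_bi0_bq, efficiency = 0.25,
                                  dt_h = 0.25, duration_h = 8, seed = 1L,
                                  collection_time_h = NA_real_,
                                  sample_id = "sample",
                                  chain = ac225_chain()) {
  if (dt_h <= 0 || duration_h < dt_h) {
    abort_acdosim("need duration_h >= dt_h > 0", "acdosim_invalid_input")
  }
  nbin <- floor(duration_h / dt_h)
  t_mid <- (seq_len(nbin) - 0.5) * dt_h
  if (is.infinite(efficiency)) {
    a <- bateman_bi_activity(t_mid, a_ac0_bq, a_bi0_bq, chain)
    return(counting_series(t_mid, a, unit = "bq", dt_h = dt_h,
                           sample_id = sample_id,
                           collection_time_h = collection_time_h))
  }
  expected <- efficiency * 3600 * dt_h *
    bateman_bi_bin_average(t_mid, dt_h, a_ac0_bq, a_bi0_bq, chain)
  counts <- with_seed(derive_seed(seed, "urine"),
                      stats::rpois(nbin, expected))
  counting_series(t_mid, counts, unit = "counts", dt_h = dt_h,
                  efficiency = efficiency, sample_id = sample_id,
                  collection_time_h = collection_time_h)
}
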