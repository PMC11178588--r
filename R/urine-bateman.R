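#' @title Urine gamma-counter series: Bateman fitting and cohort ratios
#' @description
#' A urine aliquot measured continuously in a gamma counter shows the Bi-213
#' activity as the sum of ingrowth from the Ac-225 in the sample and decay of
#' the Bi-213 present at collection (see [bateman_bi_activity()]). Fitting
#' that model to the counting series recovers both amplitudes at collection
#' time and hence the Bi-213-to-Ac-225 ratio, which is identifiable even when
#' the absolute counting efficiency is unknown.
#' @name urine_bateman
NULL

#' Construct a gamma-counter series
#'
#' @param t_h times since sample collection, hours (sorted, >= 0).
#' @param measured counts per bin, or activities in Bq when `unit = "bq"`.
#' @param unit `"counts"` or `"bq"`.
#' @param dt_h counting-bin width in hours (required for counts).
#' @param efficiency detected counts per decay in the window (optional; when
#'   absent, count data are fitted on an arbitrary scale).
#' @param sample_id,collection_time_h,window_kev sample metadata.
#' @return a `counting_series`.
#' @export
counting_series <- function(t_h, measured, unit = c("counts", "bq"),
                            dt_h = NA_real_, efficiency = NA_real_,
                            sample_id = "sample", collection_time_h = NA_real_,
                            window_kev = 440) {
  unit <- match.arg(unit)
  if (length(t_h) != length(measured)) {
    abort_acdosim("t_h and measured must have equal length", "acdosim_invalid_input")
  }
  if (is.unsorted(t_h) || any(t_h < 0)) {
    abort_acdosim("times must be sorted and non-negative", "acdosim_invalid_input")
  }
  if (any(measured < 0)) {
    abort_acdosim("measured values must be non-negative", "acdosim_invalid_input")
  }
  if (unit == "counts" && !is.finite(dt_h)) {
    abort_acdosim("count data need the bin width dt_h", "acdosim_invalid_input")
  }
  structure(list(t_h = t_h, measured = measured, unit = unit, dt_h = dt_h,
                 efficiency = efficiency, sample_id = sample_id,
                 collection_time_h = collection_time_h, window_kev = window_kev),
            class = "counting_series")
}

#' Fit the two-component Bateman model to a counting series
#'
#' Bound-constrained (>= 0) nonlinear least squares of the ingrowth-plus-decay
#' model for Bi-213. Count data are fitted with the bin-averaged forward model
#' and Poisson weights (sigma = sqrt(counts)); pre-calibrated activities are
#' fitted unweighted with the instantaneous model. When the counting
#' efficiency is unknown the amplitudes are reported on the arbitrary
#' measurement scale (`arbitrary_scale = TRUE`); the Bi/Ac ratio is
#' scale-invariant and remains trustworthy.
#'
#' @param series a `counting_series` spanning at least 5 points and about
#'   three Bi-213 half-lives (~2.3 h); at least 6 h is recommended so secular
#'   equilibrium is reached within the measurement.
#' @param chain a `decay_chain`.
#' @return a `urine_fit`: `a_ac0_bq`, `a_bi0_bq`, `bi_ac_ratio`, `vcov`
#'   (2x2, on the reported scale), `residual_norm`, `arbitrary_scale`,
#'   `at_bound`, plus the sample metadata.
#' @export
fit_urine_series <- function(series, chain = ac225_chain()) {
  t <- series$t_h
  if (length(t) < 5L || (max(t) - min(t)) < 3 * chain_nuclide("Bi-213", chain)$half_life_h) {
    abort_acdosim("series too short: need >= 5 points spanning >= 3 Bi-213 half-lives",
                  "acdosim_insufficient_data")
  }
  counts_mode <- series$unit == "counts"
  have_eff <- is.finite(series$efficiency)
  if (counts_mode) {
    # expected counts per bin = eff * decays in bin = eff * 3600 * dt * Abar(t)
    scale <- if (have_eff) series$efficiency * 3600 * series$dt_h else 1
    y <- series$measured / scale
    # Poisson: var(counts) = E[counts]; on the y scale var = counts/scale^2.
    # Weight by 1/counts (relative), which is scale-free.
    w <- 1 / pmax(series$measured, 1)
    forward <- function(t, ac, bi) bateman_bi_bin_average(t, series$dt_h, ac, bi, chain)
  } else {
    y <- series$measured
    w <- NULL
    forward <- function(t, ac, bi) bateman_bi_activity(t, ac, bi, chain)
  }
  # starting values: late points are equilibrium (~Ac), early excess is Bi
  req <- equilibrium_ratio(chain)
  l_ac <- chain_nuclide("Ac-225", chain)$decay_constant_h
  ac_start <- max(mean(y[t >= max(t) - 1]) / req * exp(l_ac * max(t)), 1e-9)
  bi_start <- max(y[1] - ac_start * (1 - exp(-0.9 * t[1])), ac_start * 0.5)
  args <- list(y ~ forward(t, ac, bi),
               start = list(ac = ac_start, bi = bi_start),
               lower = c(ac = 0, bi = 0),
               control = minpack.lm::nls.lm.control(maxiter = 500),
               data = environment())
  if (!is.null(w)) args$weights <- w
  fit <- do.call(minpack.lm::nlsLM, args)
  cf <- stats::coef(fit)
  at_bound <- any(cf <= 1e-12 * max(cf, 1))
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  arb <- counts_mode && !have_eff
  structure(list(
    a_ac0_bq = cf[["ac"]], a_bi0_bq = cf[["bi"]],
    bi_ac_ratio = cf[["bi"]] / cf[["ac"]],
    vcov = vc,
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    arbitrary_scale = arb,
    at_bound = at_bound,
    sample_id = series$sample_id,
    collection_time_h = series$collection_time_h
  ), class = "urine_fit")
}

#' Bi-213-to-Ac-225 activity ratio at collection
#'
#' @param fit a `urine_fit` (or any list with `a_ac0_bq`, `a_bi0_bq`).
#' @return dimensionless ratio `a_bi0 / a_ac0`.
#' @export
bi_ac_ratio_at <- function(fit) {
  if (fit$a_ac0_bq <= 0) {
    abort_acdosim("Ac-225 amplitude is zero; ratio undefined",
                  "acdosim_undefined_ratio")
  }
  fit$a_bi0_bq / fit$a_ac0_bq
}

#' Cohort summary of urine Bi/Ac ratios at two collection epochs
#'
#' Every patient contributes one ratio per epoch (nominally ~24 and ~48 h
#' post-injection). Reports per-epoch mean and population standard deviation
#' (divide-by-n), the mean per-patient ratio difference expressed in
#' percentage points, and (as a secondary convention) the mean per-patient
#' relative change in percent.
#'
#' @param patient patient identifiers.
#' @param epoch epoch labels (exactly two distinct values; their sorted order
#'   defines epoch 1 and epoch 2).
#' @param ratio Bi/Ac ratio per patient and epoch.
#' @return a `ratio_summary` list with `per_patient` (wide data.frame),
#'   `epoch_mean`, `epoch_sd`, `mean_change_points`, `sd_change_points`,
#'   `mean_relative_change_pct`.
#' @export
cohort_ratio_summary <- function(patient, epoch, ratio) {
  df <- data.frame(patient = as.character(patient), epoch = as.character(epoch),
                   ratio = ratio)
  levels <- sort(unique(df$epoch))
  if (length(levels) != 2L) {
    abort_acdosim("exactly two collection epochs are required", "acdosim_pairing_error")
  }
  wide <- stats::reshape(df, idvar = "patient", timevar = "epoch",
                         direction = "wide")
  names(wide) <- sub("^ratio\\.", "", names(wide))
  if (any(is.na(wide[[levels[1]]])) || any(is.na(wide[[levels[2]]]))) {
    abort_acdosim("every patient needs one ratio per epoch", "acdosim_pairing_error")
  }
  r1 <- wide[[levels[1]]]; r2 <- wide[[levels[2]]]
  diff_pts <- (r2 - r1) * 100
  structure(list(
    per_patient = wide,
    epochs = levels,
    epoch_mean = c(mean(r1), mean(r2)),
    epoch_sd = c(pop_sd(r1), pop_sd(r2)),
    mean_change_points = mean(diff_pts),
    sd_change_points = pop_sd(diff_pts),
    mean_relative_change_pct = mean((r2 / r1 - 1) * 100)
  ), class = "ratio_summary")
}
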