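#' @title Mono-exponential time-activity fitting
#' @description
#' Total VOI activities at the imaging time points are fitted with
#' \deqn{A(t) = A(t_0) \, e^{-\ln(2) t / T_{1/2}},}
#' where the effective half-life combines physical decay and biological
#' clearance, \eqn{1/T_{eff} = 1/T_{phys} + 1/T_{bio}}. With exactly two time
#' points (the common two-scan protocol) the fit is the exact interpolation
#' in closed form; with more points an unweighted (optionally 1/sigma^2
#' weighted) nonlinear least squares is used.
#' @name kinetics
NULL

#' Fit a mono-exponential time-activity curve
#'
#' @param time_h acquisition times, hours post-injection (>= 2 distinct).
#' @param activity_bq total VOI activity at each time, Bq (> 0).
#' @param sigma_bq optional per-point standard deviations for 1/sigma^2
#'   weighting (ignored for two-point fits, which are exact).
#' @return a `monoexp_fit` with `a_t0_bq` (amplitude extrapolated to t = 0),
#'   `t_eff_h`, `n_points` and `residual_norm_bq` (0 for two points).
#' @export
fit_monoexp <- function(time_h, activity_bq, sigma_bq = NULL) {
  if (length(time_h) != length(activity_bq) || length(time_h) < 2L) {
    abort_acdosim("need at least two (time, activity) points", "acdosim_invalid_input")
  }
  if (anyDuplicated(time_h)) {
    abort_acdosim("duplicate acquisition times", "acdosim_invalid_input")
  }
  if (any(time_h < 0) || any(activity_bq <= 0)) {
    abort_acdosim("times must be >= 0 and activities > 0", "acdosim_invalid_input")
  }
  ord <- order(time_h)
  t <- time_h[ord]; a <- activity_bq[ord]
  if (length(t) == 2L) {
    if (a[1] <= a[2]) {
      abort_acdosim("activity does not decay between the two time points",
                    "acdosim_non_decaying_tac")
    }
    t_eff <- (t[2] - t[1]) * log(2) / log(a[1] / a[2])
    a_t0 <- a[1] * 2^(t[1] / t_eff)
    return(structure(list(a_t0_bq = a_t0, t_eff_h = t_eff, n_points = 2L,
                          residual_norm_bq = 0), class = "monoexp_fit"))
  }
  # start values from log-linear regression
  lmfit <- stats::lm(log(a) ~ t)
  slope <- stats::coef(lmfit)[[2]]
  if (slope >= 0) {
    abort_acdosim("activity does not decay over the series", "acdosim_non_decaying_tac")
  }
  start <- list(a0 = exp(stats::coef(lmfit)[[1]]), teff = -log(2) / slope)
  args <- list(a ~ a0 * 2^(-t / teff), start = start,
               lower = c(a0 = 1e-300, teff = 1e-12),
               control = minpack.lm::nls.lm.control(maxiter = 200),
               data = environment())
  if (!is.null(sigma_bq)) args$weights <- 1 / sigma_bq[ord]^2
  fit <- do.call(minpack.lm::nlsLM, args)
  cf <- stats::coef(fit)
  structure(list(a_t0_bq = cf[["a0"]], t_eff_h = cf[["teff"]],
                 n_points = length(t),
                 residual_norm_bq = sqrt(sum(stats::resid(fit)^2))),
            class = "monoexp_fit")
}

#' Evaluate a fitted mono-exponential
#' @param fit a `monoexp_fit`.
#' @param time_h times, hours.
#' @return activity in Bq.
#' @export
predict_monoexp <- function(fit, time_h) {
  fit$a_t0_bq * 2^(-time_h / fit$t_eff_h)
}

#' Decompose an effective half-life into physical and biological components
#'
#' From \eqn{\lambda_{eff} = \lambda_{bio} + \lambda_{phys}}:
#' `lambda_bio = lambda_eff - lambda_phys`, `T_bio = ln(2)/lambda_bio`.
#' An effective half-life at or above the physical one implies non-positive
#' biological clearance and is rejected.
#'
#' @param t_eff_h effective half-life, hours.
#' @param parent a `nuclide` (or its name) whose physical half-life applies.
#' @param chain a `decay_chain`, used when `parent` is given by name.
#' @return list with `t_eff_h`, `t_phys_h`, `t_bio_h`, `lambda_bio_h`,
#'   `lambda_phys_h`.
#' @export
biological_half_life <- function(t_eff_h, parent = "Ac-225", chain = ac225_chain()) {
  stopifnot_scalar_positive(t_eff_h, "t_eff_h")
  if (is.character(parent)) parent <- chain_nuclide(parent, chain)
  t_phys <- parent$half_life_h
  if (t_eff_h >= t_phys) {
    abort_acdosim("effective half-life must be below the physical half-life",
                  "acdosim_non_physical_kinetics")
  }
  l_phys <- log(2) / t_phys
  l_eff <- log(2) / t_eff_h
  l_bio <- l_eff - l_phys
  list(t_eff_h = t_eff_h, t_phys_h = t_phys, t_bio_h = log(2) / l_bio,
       lambda_bio_h = l_bio, lambda_phys_h = l_phys)
}

#' Time-integrated activity of a fitted TAC
#'
#' Integral of the fitted exponential from `from_h` to infinity,
#' \eqn{\tilde A = A(t_0) T_{eff} / \ln 2 \cdot 2^{-from/T_{eff}}}. The
#' default lower bound 0 extrapolates the fit back to injection, treating the
#' uptake phase before the first scan as instantaneous (standard MIRD
#' practice when no early imaging exists).
#'
#' @param fit a `monoexp_fit`.
#' @param from_h lower integration bound, hours (default 0).
#' @return time-integrated activity in Bq·h.
#' @export
time_integrated_activity <- function(fit, from_h = 0) {
  if (from_h < 0) abort_acdosim("lower bound must be >= 0", "acdosim_invalid_input")
  fit$a_t0_bq * fit$t_eff_h / log(2) * 2^(-from_h / fit$t_eff_h)
}
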