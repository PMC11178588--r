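# Table of per-patient urine activity concentrations (Bq/ml) at the two
# collection epochs used in the cohort-summary checks.
urine_cohort <- data.frame(
  patient = rep(paste0("patient_", 1:5), 2),
  epoch = rep(c("24h", "48h"), each = 5),
  ac = c(242.6, 232.9, 61.1, 303.9, 128.6, 38.7, 38.8, 44.1, 42.9, 113.2),
  bi = c(218.9, 248.3, 76.0, 250.6, 113.3, 41.7, 40.3, 55.7, 43.3, 115.6))

test_that("noiseless series are recovered essentially exactly", {
  s <- simulate_urine_series(100, 90, efficiency = Inf, dt_h = 0.1,
                             duration_h = 8)
  fit <- fit_urine_series(s)
  expect_equal(fit$a_ac0_bq, 100, tolerance = 1e-8)
  expect_equal(fit$a_bi0_bq, 90, tolerance = 1e-8)
  expect_equal(bi_ac_ratio_at(fit), 0.9, tolerance = 1e-8)
  expect_false(fit$arbitrary_scale)
  # forward model at the fitted parameters reproduces the series
  pred <- bateman_bi_activity(s$t_h, fit$a_ac0_bq, fit$a_bi0_bq)
  expect_equal(pred, s$measured, tolerance = 1e-8)
})

test_that("per-sample amplitude pairs reproduce the tabulated ratios", {
  # patient 3 at 22.0 h: 61.1 / 76.0 Bq/ml, ratio 1.24
  s <- simulate_urine_series(61.1, 76.0, efficiency = Inf, dt_h = 0.1,
                             duration_h = 8)
  fit <- fit_urine_series(s)
  expect_equal(round(bi_ac_ratio_at(fit), 2), 1.24)
  # patient 1 at 17.0 h: 242.6 / 218.9 Bq/ml, ratio 0.90
  expect_equal(round(218.9 / 242.6, 2), 0.90)
  fit2 <- list(a_ac0_bq = 242.6, a_bi0_bq = 218.9)
  expect_equal(round(bi_ac_ratio_at(fit2), 2), 0.90)
  expect_equal(bi_ac_ratio_at(list(a_ac0_bq = 10, a_bi0_bq = 0)), 0)
  expect_error(bi_ac_ratio_at(list(a_ac0_bq = 0, a_bi0_bq = 1)),
               class = "acdosim_undefined_ratio")
})

test_that("the ratio is identifiable without an efficiency calibration", {
  s <- simulate_urine_series(150, 140, efficiency = 0.3, dt_h = 0.25,
                             duration_h = 8, seed = 12)
  # strip the efficiency: amplitudes become arbitrary, ratio must not change
  s_unknown <- counting_series(s$t_h, s$measured, unit = "counts",
                               dt_h = s$dt_h, efficiency = NA_real_)
  f_known <- fit_urine_series(s)
  f_unknown <- fit_urine_series(s_unknown)
  expect_true(f_unknown$arbitrary_scale)
  expect_equal(bi_ac_ratio_at(f_unknown), bi_ac_ratio_at(f_known),
               tolerance = 1e-6)
  # and a global rescaling of a calibrated series leaves the ratio unchanged
  s_scaled <- counting_series(s$t_h, s$measured * 7, unit = "counts",
                              dt_h = s$dt_h, efficiency = NA_real_)
  f_scaled <- fit_urine_series(s_scaled)
  expect_equal(bi_ac_ratio_at(f_scaled), bi_ac_ratio_at(f_unknown),
               tolerance = 1e-6)
})

test_that("short series are rejected", {
  s <- simulate_urine_series(100, 90, efficiency = Inf, dt_h = 0.5,
                             duration_h = 1.5)
  expect_error(fit_urine_series(s), class = "acdosim_insufficient_data")
})

test_that("recovered ratios are unbiased across the physiological range", {
  # sweep the truth ratio over [0.5, 1.5]; Poisson counting noise
  ratios <- c(0.5, 0.75, 1.0, 1.25, 1.5)
  reps <- 40
  bias <- vapply(ratios, function(r) {
    est <- vapply(seq_len(reps), function(i) {
      s <- simulate_urine_series(200, 200 * r, efficiency = 0.25, dt_h = 0.25,
                                 duration_h = 8, seed = 1000 * r + i)
      bi_ac_ratio_at(fit_urine_series(s))
    }, 0)
    mean(est) - r
  }, 0)
  # Monte-Carlo error of each mean is ~sd/sqrt(reps) ~ 0.01; allow 3 sigma
  expect_true(all(abs(bias) < 0.03))
})

test_that("cohort ratio summary uses population SD and percentage points", {
  r <- urine_cohort$bi / urine_cohort$ac
  s <- cohort_ratio_summary(urine_cohort$patient, urine_cohort$epoch, r)
  expect_equal(round(s$epoch_mean, 2), c(0.98, 1.08))
  expect_equal(round(s$epoch_sd, 2), c(0.15, 0.09))
  expect_equal(round(s$mean_change_points), 10)
  expect_equal(round(s$sd_change_points), 9)
  # identical ratios at both epochs: zero change
  s0 <- cohort_ratio_summary(urine_cohort$patient, urine_cohort$epoch,
                             rep(urine_cohort$bi[1:5] / urine_cohort$ac[1:5], 2))
  expect_equal(s0$mean_change_points, 0)
  # an unpaired patient is an error
  expect_error(cohort_ratio_summary(c("a", "a", "b"), c("24h", "48h", "24h"),
                                    c(1, 1.1, 0.9)),
               class = "acdosim_pairing_error")
})
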