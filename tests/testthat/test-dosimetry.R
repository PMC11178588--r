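test_that("local alpha S values follow the energy / mass conversion", {
  seg1 <- structure(list(label = "unit", members = "Ac-225", surrogate = NA),
                    class = "chain_segment")
  # 1 MeV per decay in 1 g: 1.602e-13 J / 1e-3 kg
  ch <- ac225_chain()
  ch_mod <- ch
  ch_mod$nuclides[["Ac-225"]]$alpha_emissions <-
    data.frame(energy_mev = 1, probability = 1)
  expect_equal(local_alpha_svalue(seg1, 1, ch_mod), 1.602e-10, tolerance = 1e-12)

  expect_equal(local_alpha_svalue(chain_segment("Bi"), 23), 5.81e-11,
               tolerance = 1e-3)
  # halving with mass
  s100 <- local_alpha_svalue(chain_segment("full"), 100)
  expect_equal(local_alpha_svalue(chain_segment("full"), 200), s100 / 2)
  expect_error(local_alpha_svalue(chain_segment("Bi"), 0),
               class = "acdosim_invalid_input")
})

test_that("a TAC constructed as 1/S delivers exactly 1 Gy", {
  mass <- 150
  s <- local_alpha_svalue(chain_segment("full"), mass)
  # choose A(t0) so that the Bq·s integral is 1/S
  teff <- 27
  a0 <- 1 / s / (teff * 3600 / log(2))
  fit <- structure(list(a_t0_bq = a0, t_eff_h = teff), class = "monoexp_fit")
  d <- dose_method1(fit, mass)
  expect_equal(d$absorbed_gy, 1, tolerance = 1e-12)
  expect_equal(d$sv_rbe, 5, tolerance = 1e-12)
})

test_that("identical TACs make the three methods coincide", {
  fit <- fit_monoexp(c(24, 48), c(5e4, 2.6e4))
  mass <- 247
  d1 <- dose_method1(fit, mass, injected_mbq = 7.9)
  d2 <- dose_method2(fit, mass, injected_mbq = 7.9)
  d3 <- dose_method3(fit, fit, mass, injected_mbq = 7.9)
  expect_equal(d1$absorbed_gy, d2$absorbed_gy, tolerance = 1e-12)
  expect_equal(d1$absorbed_gy, d3$absorbed_gy, tolerance = 1e-12)
  expect_equal(d1$sv_rbe_per_mbq, d3$sv_rbe_per_mbq, tolerance = 1e-12)
  # partition additivity: the segment components of method 3 sum to method 1
  expect_equal(sum(d3$components$absorbed_gy), d1$absorbed_gy, tolerance = 1e-12)
})

test_that("method 3 interpolates methods 1 and 2 when kinetics differ", {
  a0 <- 1e5; mass <- 200
  bi_fit <- structure(list(a_t0_bq = a0, t_eff_h = 27), class = "monoexp_fit")
  fr_fit <- structure(list(a_t0_bq = a0, t_eff_h = 24), class = "monoexp_fit")
  d1 <- dose_method1(bi_fit, mass)
  d2 <- dose_method2(fr_fit, mass)
  d3 <- dose_method3(fr_fit, bi_fit, mass)
  expect_gt(d1$absorbed_gy, d3$absorbed_gy)  # Bi TAC integrates higher
  expect_gt(d3$absorbed_gy, d2$absorbed_gy)
  # hand-computed spreadsheet value
  tia <- function(f) f$a_t0_bq * f$t_eff_h / log(2) * 3600
  expected <- tia(fr_fit) * local_alpha_svalue(chain_segment("Fr"), mass) +
    tia(bi_fit) * local_alpha_svalue(chain_segment("Bi"), mass)
  expect_equal(d3$absorbed_gy, expected, tolerance = 1e-12)
})

test_that("dose is linear in amplitude and RBE weighting commutes with per-MBq", {
  fit <- structure(list(a_t0_bq = 2e5, t_eff_h = 38), class = "monoexp_fit")
  fit2 <- fit; fit2$a_t0_bq <- 4e5
  d <- dose_method1(fit, 23, injected_mbq = 7.4)
  d2 <- dose_method1(fit2, 23, injected_mbq = 7.4)
  expect_equal(d2$absorbed_gy, 2 * d$absorbed_gy, tolerance = 1e-12)
  expect_equal(d$sv_rbe_per_mbq, d$rbe * d$absorbed_gy / 7.4, tolerance = 1e-12)
  expect_equal(d$sv_rbe, d$rbe * d$absorbed_gy, tolerance = 1e-12)
})

test_that("an S-value table mirroring local alpha absorption reproduces alpha_local", {
  ch <- ac225_chain()
  masses <- c(23, 100, 247)
  rows <- do.call(rbind, lapply(ch$order, function(nm) {
    al <- ch$nuclides[[nm]]$alpha_emissions
    e <- if (nrow(al)) sum(al$energy_mev * al$probability) else 0
    data.frame(nuclide = nm, mass_g = masses,
               s_gy_per_bq_s = e * 1.602e-13 / (masses * 1e-3),
               alpha_fraction = 1)
  }))
  tab <- svalue_table(rows, provenance = "synthetic local-alpha table")
  cfg_tab <- dose_config(energy_model = "svalue_table", svalue_table = tab)
  cfg_loc <- dose_config()
  bi_fit <- fit_monoexp(c(24, 48), c(8e4, 4.3e4))
  fr_fit <- fit_monoexp(c(24, 48), c(8e4, 4.0e4))
  for (mass in masses) {
    d_tab <- dose_method3(fr_fit, bi_fit, mass, cfg_tab)
    d_loc <- dose_method3(fr_fit, bi_fit, mass, cfg_loc)
    expect_equal(d_tab$absorbed_gy, d_loc$absorbed_gy, tolerance = 1e-12)
    expect_equal(d_tab$sv_rbe, d_loc$sv_rbe, tolerance = 1e-12)
  }
  # log-log mass interpolation stays within the bracket and is ~1/m
  lk <- svalue_lookup(tab, "Po-213", 150)
  expect_true(lk$interpolated)
  expect_equal(lk$s_gy_per_bq_s, 8.4 * 1.602e-13 / 0.150, tolerance = 1e-3)
  expect_error(svalue_lookup(tab, "Po-213", 1e4), class = "acdosim_lookup_error")
  expect_error(svalue_lookup(tab, "Ra-223", 100), class = "acdosim_lookup_error")
})

test_that("percent differences support both conventions and are symmetric", {
  expect_equal(method_percent_difference(0.18, 0.18), 0)
  expect_equal(method_percent_difference(0.18, 0.16), 100 * 0.02 / 0.17,
               tolerance = 1e-12)
  expect_equal(method_percent_difference(0.18, 0.16), 11.76, tolerance = 1e-3)
  expect_equal(method_percent_difference(0.18, 0.16, "relative_b"), 12.5,
               tolerance = 1e-12)
  expect_equal(method_percent_difference(0.18, 0.16),
               method_percent_difference(0.16, 0.18))
  expect_error(method_percent_difference(0, 0), class = "acdosim_undefined_ratio")
})
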