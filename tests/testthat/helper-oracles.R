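# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force exact Wilcoxon signed-rank p: enumerate all 2^n sign
# assignments of the (mid-tied) ranks and apply the two-sided
# 2 * min(P(W <= w), P(W >= w)) convention.
brute_force_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% ranks)
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

# Numerical integration of the two-nuclide decay system
# dN_ac/dt = -l_ac N_ac ; dN_bi/dt = l_ac N_ac - l_bi N_bi
# returning the Bi-213 *activity* l_bi * N_bi at the requested times.
ode_bi_activity <- function(times_h, a_ac0, a_bi0, l_ac, l_bi) {
  deriv <- function(t, y, parms) {
    list(c(-l_ac * y[1], l_ac * y[1] - l_bi * y[2]))
  }
  y0 <- c(n_ac = a_ac0 / l_ac, n_bi = a_bi0 / l_bi)
  out <- deSolve::ode(y0, c(0, times_h), deriv, parms = NULL,
                      rtol = 1e-12, atol = 1e-12)
  l_bi * out[-1, "n_bi"]
}

# Generic unstructured least squares for the mono-exponential model:
# profile out the (linear) amplitude, 1-D search over log half-life, then a
# Levenberg-Marquardt polish. Independent of the package's closed form.
generic_monoexp_ls <- function(t, a) {
  ssr <- function(lte) {
    x <- 2^(-t / exp(lte)); a0 <- sum(a * x) / sum(x * x); sum((a - a0 * x)^2)
  }
  lte <- stats::optimize(ssr, log(c(0.1, 1e6)), tol = 1e-12)$minimum
  te <- exp(lte); x <- 2^(-t / te); a0 <- sum(a * x) / sum(x * x)
  ref <- minpack.lm::nls.lm(par = list(a0 = a0, te = te),
                            fn = function(p) a - p$a0 * 2^(-t / p$te),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  c(a0 = ref$par$a0, te = ref$par$te)
}

# Small scenario used by image/workflow tests: 2 patients on a 48^3 grid.
test_scenario <- function(seed = 42L, noise = "poisson", ...) {
  cohort_scenario(seed = seed, n_patients = 2L, matrix_size = 48L,
                  noise = noise, ...)
}

# Fully noise-free variant: no Poisson noise, no system blur.
noisefree_scenario <- function(seed = 7L, ...) {
  cohort_scenario(seed = seed, n_patients = 2L, matrix_size = 48L,
                  noise = "none", psf_fwhm_mm = 0, tac_cv = 0, ...)
}
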