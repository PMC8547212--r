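# Shared oracles and fixture builders. Everything here is independent of the
# closed forms it is used to check.

# binning function by adaptive quadrature of (2/T^2) int_0^T (T - tau) g(tau) dtau
gamma_quadrature <- function(T, g, ...) {
  2 / T^2 * stats::integrate(function(tau) (T - tau) * g(tau, ...),
                             lower = 0, upper = T,
                             rel.tol = 1e-12, subdivisions = 2000L)$value
}

# Q at sampling factor f by explicit loop over reshaped blocks (brute force)
q_bruteforce <- function(counts, f) {
  n <- length(counts)
  stopifnot(n %% f == 0)
  sums <- vapply(seq_len(n %/% f), function(i) {
    sum(counts[((i - 1) * f + 1):(i * f)])
  }, numeric(1))
  m1 <- mean(sums)
  m2 <- mean(sums^2)
  (m2 - m1^2 - m1) / m1
}

poisson_trace <- function(n, lambda, bin_width = 1e-6, seed = 1) {
  set.seed(seed)
  photon_trace(stats::rpois(n, lambda), bin_width)
}

# exact model-generated mSMR curve on a log-spaced grid (for fitting tests)
model_curve <- function(params, T = 10^seq(-6, -1, length.out = 40)) {
  mu <- msmr_model(T, params)
  structure(
    data.frame(T_s = T, m1 = NA_real_, m2 = NA_real_, m3 = NA_real_,
               n_bins = NA_integer_, Q = mu * T, mu_cps = mu,
               corr_deadtime = FALSE, corr_afterpulse = FALSE,
               corr_background = FALSE),
    class = c("msmr_curve", "data.frame"), bin_width = T[1], T_obs = NA_real_)
}

# the standard simulation conditions used across simulator tests
study_sim_config <- function(mu0 = 1e5, D = 50, duration = 10, seed = 1,
                             n_particles = 20, r0 = 0.4, r = 1) {
  sim_config(sim_species(D = D, count = n_particles, mu0 = mu0),
             psf_geometry(r0, r0 * r), duration = duration, seed = seed)
}
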