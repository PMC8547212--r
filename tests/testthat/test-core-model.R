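test_that("PSF shape factors match the Gaussian closed form and a quadrature oracle", {
  geom <- psf_geometry(0.4, 2.0)
  expect_equal(gamma_factor(1, geom), 1.0)
  expect_equal(gamma_factor(2, geom), 1 / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(gamma_factor(2, geom), 0.3535533906, tolerance = 1e-9)
  expect_error(gamma_factor(0, geom), "integer >= 1")

  # independent oracle: gamma_2 = int PSF^2 / int PSF over a wide separable grid
  axis_ratio <- function(w) {
    num <- integrate(function(u) exp(-4 * u^2 / w^2), -6 * w, 6 * w,
                     rel.tol = 1e-10)$value
    den <- integrate(function(u) exp(-2 * u^2 / w^2), -6 * w, 6 * w,
                     rel.tol = 1e-10)$value
    num / den
  }
  g2_quad <- axis_ratio(0.4)^2 * axis_ratio(2.0)
  expect_equal(g2_quad, 1 / (2 * sqrt(2)), tolerance = 1e-4)
})

test_that("diffusion kernel matches direct substitution and decays monotonically", {
  expect_equal(g_diffusion_3dg(0, 1e-3), 1.0)
  expect_equal(g_diffusion_3dg(1e-3, 1e-3, r = 1), 1 / (2 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(g_diffusion_3dg(1e-3, 1e-3, r = 10), 1 / (2 * sqrt(1.01)),
               tolerance = 1e-12)
  tau <- 10^seq(-6, 0, length.out = 50)
  v <- g_diffusion_3dg(tau, 1e-3, r = 2)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 1))
  expect_error(g_diffusion_3dg(-1e-9, 1e-3), ">= 0")
})

test_that("isomerization kernel matches direct substitution", {
  expect_equal(g_isomerization(0.123, F = 0, tauF = 1e-5), 1.0)
  expect_equal(g_isomerization(0, F = 0.2, tauF = 1e-5), 1.25)
  expect_equal(g_isomerization(1e-5, F = 0.2, tauF = 1e-5), 1 + 0.25 * exp(-1),
               tolerance = 1e-12)
  expect_error(g_isomerization(1, F = 1, tauF = 1e-5), "\\[0, 1\\)")
})

test_that("closed-form diffusion binning agrees with adaptive quadrature on both branches", {
  for (r in c(1, 2, 5, 10)) {
    for (alpha in c(1e-3, 1e-2, 0.05, 1, 10, 1e3)) {
      closed <- binning_diffusion(alpha, tauD = 1, r = r)
      quad <- gamma_quadrature(alpha, g_diffusion_3dg, tauD = 1, r = r)
      expect_equal(closed, quad, tolerance = 1e-8,
                   label = sprintf("Gamma_diff(alpha=%g, r=%g)", alpha, r))
    }
  }
})

test_that("diffusion binning limits, monotonicity and frozen values hold", {
  expect_equal(binning_diffusion(1e-9, tauD = 1, r = 1), 1.0, tolerance = 1e-6)
  # r = 1, T = tauD: 8 * (1/2 - sqrt(2) + 1)
  expect_equal(binning_diffusion(1, tauD = 1, r = 1), 8 * (1.5 - sqrt(2)),
               tolerance = 1e-12)
  expect_equal(binning_diffusion(1, tauD = 1, r = 1), 0.6862915, tolerance = 1e-7)
  Tv <- 10^seq(-5, 2, length.out = 100)
  for (r in c(1, 5)) {
    v <- binning_diffusion(Tv, tauD = 1, r = r)
    expect_true(all(diff(v) < 0))
    expect_true(all(v > 0 & v <= 1))
  }
  expect_error(binning_diffusion(0, 1), "> 0")
  expect_error(binning_diffusion(1, -1), "> 0")
})

test_that("the r > 1 branch is continuous with the r = 1 branch as beta -> 1", {
  # at r = 1 + 1e-6 the true curves differ by < 7e-7 over this range
  for (alpha in 10^seq(-2, 2, length.out = 9)) {
    expect_equal(binning_diffusion(alpha, 1, r = 1 + 1e-6),
                 binning_diffusion(alpha, 1, r = 1),
                 tolerance = 1e-6)
  }
})

test_that("isomerization binning matches quadrature, series limit and asymptotes", {
  for (F in c(0.2, 0.5)) {
    for (x in c(1e-2, 0.3, 1, 10, 1e3)) {  # x = T / tauF
      closed <- binning_isomerization(x * 1e-5, F = F, tauF = 1e-5)
      quad <- gamma_quadrature(x * 1e-5, g_isomerization, F = F, tauF = 1e-5)
      expect_equal(closed, quad, tolerance = 1e-8,
                   label = sprintf("Gamma_iso(x=%g, F=%g)", x, F))
    }
  }
  expect_equal(binning_isomerization(0.37, F = 0, tauF = 1e-5), 1.0)
  expect_equal(binning_isomerization(1e-6 * 1e-5, F = 0.2, tauF = 1e-5), 1.25,
               tolerance = 1e-5)                       # T -> 0: 1/(1-F)
  expect_equal(binning_isomerization(1e4 * 1e-5, F = 0.2, tauF = 1e-5), 1,
               tolerance = 1e-3)                       # T -> Inf
  v <- binning_isomerization(10^seq(-8, -2, length.out = 60), F = 0.3, tauF = 1e-5)
  expect_true(all(diff(v) < 0))
})

test_that("mSMR and Q models compose the verified factors", {
  p <- model_params(mu0 = 1e5, tauD = 1e-3, r = 1)
  g2 <- 1 / (2 * sqrt(2))
  expect_equal(msmr_model(1e-9, p), g2 * 1e5, tolerance = 1e-3)   # plateau
  expect_equal(msmr_model(1e-9, p) / 1e3, 35.355, tolerance = 1e-3)  # kCps
  p_iso <- model_params(mu0 = 1e5, tauD = 1e-3, r = 1, F = 0.2, tauF = 1e-5)
  expect_equal(msmr_model(1e-10, p_iso), g2 * 1e5 / 0.8, tolerance = 1e-3)
  expect_equal(msmr_model(1e-10, p_iso) / 1e3, 44.194, tolerance = 1e-3)
  # frozen arithmetic composition at T = tauD
  expect_equal(q_model(1e-3, p), g2 * 1e5 * 1e-3 * 8 * (1.5 - sqrt(2)),
               tolerance = 1e-12)
  expect_equal(q_model(1e-3, p), 24.264, tolerance = 1e-4)
  # identity Q(T) = T * mu(T) on random parameter draws
  set.seed(42)
  for (i in 1:20) {
    pr <- model_params(mu0 = runif(1, 1e3, 1e6), tauD = 10^runif(1, -5, -2),
                       r = runif(1, 1, 10), F = runif(1, 0, 0.8),
                       tauF = 10^runif(1, -7, -4))
    Tv <- 10^runif(3, -7, -1)
    expect_equal(q_model(Tv, pr), Tv * msmr_model(Tv, pr), tolerance = 1e-14)
  }
})

test_that("parameter containers enforce their invariants", {
  expect_error(psf_geometry(0.4, 0.2), "< 1")
  expect_error(psf_geometry(-0.4, 1), "positive")
  expect_error(model_params(mu0 = -1, tauD = 1e-3), "> 0")
  expect_error(model_params(mu0 = 1, tauD = 1e-3, F = 1), "\\[0, 1\\)")
  g <- psf_geometry(0.4, 2.0)
  expect_equal(g$r, 5)
  expect_equal(g$beta, 1 / 25)
})
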