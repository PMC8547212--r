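test_that("time slice and per-species steps follow the Einstein-Smoluchowski relation", {
  geom <- psf_geometry(0.4, 0.4)
  cfg <- sim_config(sim_species(D = 50, count = 20, mu0 = 1e5), geom, duration = 1)
  ts <- time_slice(cfg)
  expect_equal(ts$delta_t, (0.02)^2 / (6 * 50), tolerance = 1e-12)  # 1.3333e-6 s
  expect_equal(ts$delta_t, 1.3333e-6, tolerance = 1e-4)
  expect_equal(ts$step_um, 0.02)  # single species: step = max step exactly

  cfg2 <- sim_config(list(sim_species(50, 10, 1e5), sim_species(12.5, 10, 1e5)),
                     geom, duration = 1)
  ts2 <- time_slice(cfg2)
  expect_equal(ts2$step_um, c(0.02, 0.01), tolerance = 1e-12)  # 20 nm and 10 nm

  cfg0 <- sim_config(sim_species(0, 5, 1e5), geom, duration = 1)
  expect_error(time_slice(cfg0), "delta_t")
})

test_that("PSF evaluation matches the Gaussian profile", {
  geom <- psf_geometry(0.4, 2.0)
  expect_equal(psf_value(c(0, 0, 0), geom), 1.0)
  expect_equal(psf_value(c(0.4, 0, 0), geom), exp(-2), tolerance = 1e-12)
  expect_equal(psf_value(c(0, 0, 2.0), geom), exp(-2), tolerance = 1e-12)
  expect_equal(psf_value(c(0.4 / sqrt(2), 0.4 / sqrt(2), 0), geom), exp(-2),
               tolerance = 1e-12)
})

test_that("identical seed and config give a bit-identical trace", {
  cfg <- study_sim_config(duration = 0.05, seed = 77)
  t1 <- simulate_trace(cfg)
  t2 <- simulate_trace(cfg)
  expect_identical(t1$counts, t2$counts)
  t3 <- simulate_trace(study_sim_config(duration = 0.05, seed = 78))
  expect_false(identical(t1$counts, t3$counts))
})

test_that("dark emitters produce an all-zero trace", {
  cfg <- sim_config(sim_species(D = 50, count = 5, mu0 = 0),
                    psf_geometry(0.4, 0.4), duration = 0.01, seed = 1)
  expect_true(all(simulate_trace(cfg)$counts == 0))
})

test_that("an immobile particle at the PSF maximum emits i.i.d. Poisson counts", {
  cfg <- sim_config(sim_species(D = 0, count = 1, mu0 = 1e5),
                    psf_geometry(0.4, 0.4), duration = 0.5,
                    delta_t = 1e-6, seed = 13,
                    init_positions = matrix(0, 3, 1))
  tr <- simulate_trace(cfg)
  n <- length(tr$counts)
  lambda <- 0.1  # mu0 * delta_t
  expect_equal(mean(tr$counts), lambda, tolerance = 5 * sqrt(lambda / n) / lambda)
  m <- raw_moments(tr)
  expect_lt(abs(mandel_q(m[["m1"]], m[["m2"]])), 5 * sqrt(2 / n))
})

test_that("the long-run count rate matches the analytic box average of the PSF", {
  cfg <- study_sim_config(duration = 2, seed = 101)
  tr <- simulate_trace(cfg)
  expected_rate <- 20 * 1e5 * psf_box_average(psf_geometry(0.4, 0.4))
  observed_rate <- sum(tr$counts) / (length(tr) * tr$bin_width)
  # blocked standard error: 40 blocks of 50 ms >> tauD = 0.8 ms
  blocks <- rebin(tr, length(tr) / 40)$counts / (2 / 40)
  se <- sd(blocks) / sqrt(40)
  expect_lt(abs(observed_rate - expected_rate), 5 * se)
})

test_that("uniformly pinned emitters give the superpoissonian Poisson-mixture Q", {
  # diffusion off: the trace is a uniform mixture of Poissons over the box;
  # Q_mix = Var(lambda)/E(lambda) with lambda = mu0 dt PSF(r)
  geom <- psf_geometry(0.4, 0.4)
  m <- 12
  set.seed(55)
  P <- 30
  pos <- rbind(runif(P, -m * 0.4 / 2, m * 0.4 / 2),
               runif(P, -m * 0.4 / 2, m * 0.4 / 2),
               runif(P, -m * 0.4 / 2, m * 0.4 / 2))
  dt <- 1e-6
  cfg <- sim_config(sim_species(D = 0, count = P, mu0 = 2e5), geom,
                    duration = 0.5, delta_t = dt, seed = 14,
                    init_positions = pos)
  tr <- simulate_trace(cfg)
  lam <- 2e5 * dt * psf_value(pos, geom)
  # per-slice total is Poisson(sum(lam)): for FIXED positions Q = 0; the
  # mixture dispersion appears across the ensemble, so test the Poisson null
  # of the pinned configuration (Q >= 0 up to sampling error, here = 0)
  mm <- raw_moments(tr)
  q <- mandel_q(mm[["m1"]], mm[["m2"]])
  expect_equal(mean(tr$counts), sum(lam),
               tolerance = 5 * sqrt(sum(lam) / length(tr)) / sum(lam))
  expect_gt(q, -5 * sqrt(2 / length(tr)))
  expect_lt(q, 5 * sqrt(2 / length(tr)))
})

test_that("blinking emitters produce the on/off signature and the dark fraction is recovered", {
  # k_on = 4e4/s, k_off = 1e4/s: F = 0.2, tauF = 2e-5 s
  cfg <- sim_config(sim_species(D = 50, count = 20, mu0 = 1e5),
                    psf_geometry(0.4, 0.4), duration = 4, seed = 202,
                    blinking = list(k_on = 4e4, k_off = 1e4))
  tr <- simulate_trace(cfg)
  cur <- msmr_curve(tr)
  init <- model_params(1e5, 8e-4, r = 1, F = 0.15, tauF = 3e-5)
  fit_iso <- fit_msmr(cur, initial = init, fixed = "r", include_iso = TRUE)
  fit_diff <- fit_msmr(cur, initial = init, fixed = "r", include_iso = FALSE)
  expect_true(fit_iso$converged)
  # the isomerization term is needed to describe the short-T rise
  expect_lt(fit_iso$residual_norm, 0.8 * fit_diff$residual_norm)
  expect_equal(fit_iso$params$F, 0.2, tolerance = 0.5)
  # under the standard-model normalization a blinking emitter fits an
  # effective brightness near mu0 * (1 - F)
  expect_equal(fit_iso$params$mu0, 1e5 * 0.8, tolerance = 0.15)
})
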