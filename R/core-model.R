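#' PSF shape factor gamma_r
#'
#' Ratio of the r-th power integral of the normalized PSF to its plain integral.
#' For the 3D Gaussian PSF the closed form is `gamma_r = r^(-3/2)`, so
#' `gamma_1 = 1` and `gamma_2 = 1/(2*sqrt(2))` independent of the volume's
#' aspect ratio.
#'
#' @param order Cumulant order, integer >= 1 (only 1 and 2 are used here).
#' @param geometry A [psf_geometry()]; accepted for interface symmetry, the
#'   Gaussian closed form does not depend on it.
#' @return Dimensionless shape factor.
#' @examples
#' gamma_factor(2)  # 1/(2*sqrt(2)) = 0.3535534
#' @export
gamma_factor <- function(order, geometry = NULL) {
  if (!is.numeric(order) || length(order) != 1L || order < 1 || order != round(order))
    stop("`order` must be an integer >= 1")
  order^(-3 / 2)
}

#' Diffusion correlation kernel for a 3D Gaussian PSF
#'
#' `g(tau) = [(1 + tau/tauD) * sqrt(1 + tau/(r^2 tauD))]^-1`, the normalized
#' concentration-fluctuation correlation of free 3D diffusion through a
#' Gaussian volume. Equals 1 at `tau = 0` and decays monotonically.
#'
#' @param tau Lag time(s), seconds, >= 0. Vectorized.
#' @param tauD Mean diffusion time, seconds.
#' @param r Axial/lateral PSF ratio, >= 1.
#' @return Correlation value(s) in (0, 1].
#' @export
g_diffusion_3dg <- function(tau, tauD, r = 1) {
  if (any(tau < 0)) stop("`tau` must be >= 0")
  if (tauD <= 0) stop("`tauD` must be > 0")
  if (r < 1) stop("`r` must be >= 1")
  u <- tau / tauD
  1 / ((1 + u) * sqrt(1 + u / r^2))
}

#' On/off isomerization correlation kernel
#'
#' `g(t) = 1 + F/(1-F) * exp(-t/tauF)` for a binary bright/dark system with
#' dark fraction `F` and relaxation time `tauF = 1/(k_on + k_off)`.
#'
#' @param t Lag time(s), seconds, >= 0. Vectorized.
#' @param F Dark-state fraction in `[0, 1)`.
#' @param tauF Relaxation time, seconds.
#' @return Correlation value(s), >= 1, decaying to 1 as `t -> Inf`.
#' @export
g_isomerization <- function(t, F, tauF) {
  if (any(t < 0)) stop("`t` must be >= 0")
  if (F < 0 || F >= 1) stop("`F` must be in [0, 1): prefactor diverges at F = 1")
  if (tauF <= 0) stop("`tauF` must be > 0")
  1 + F / (1 - F) * exp(-t / tauF)
}

# Small-alpha series of the diffusion binning function, valid for any beta in
# (0, 1]: Gamma = 1 - c1*a/3 + c2*a^2/6 - c3*a^3/10 + c4*a^4/15 with
# c_k the Taylor coefficients of g_3DG in tau/tauD.
.gamma_diff_series <- function(alpha, beta) {
  c1 <- 1 + beta / 2
  c2 <- c1 + 3 * beta^2 / 8
  c3 <- c2 + 5 * beta^3 / 16
  c4 <- c3 + 35 * beta^4 / 128
  1 - c1 * alpha / 3 + c2 * alpha^2 / 6 - c3 * alpha^3 / 10 + c4 * alpha^4 / 15
}

#' Diffusion binning function for a 3D Gaussian PSF
#'
#' The dimensionless binning function
#' `Gamma(T) = (2/T^2) * integral_0^T (T - tau) g(tau) dtau` evaluated in
#' closed form for the 3D Gaussian diffusion kernel, with
#' `alpha = T/tauD` and `beta = 1/r^2`:
#' the `r = 1` branch is `(8/alpha^2) (alpha/2 - sqrt(1+alpha) + 1)`; the
#' `r > 1` branch uses the artanh form. Decreases monotonically from 1 at
#' `T -> 0` towards 0.
#'
#' Numerics: a series expansion is used for `alpha < 0.02` (both branches lose
#' ~all significant digits to cancellation there), and the `r = 1` branch is
#' taken when `|beta - 1| < 1e-6` since the artanh branch is 0/0 at `beta = 1`.
#' An artanh argument outside (-1, 1) raises an error rather than clamping.
#'
#' @param T Sampling time(s), seconds, > 0. Vectorized.
#' @param tauD Mean diffusion time, seconds.
#' @param r Axial/lateral PSF ratio, >= 1.
#' @return Binning factor(s) in (0, 1].
#' @examples
#' binning_diffusion(8e-4, tauD = 8e-4, r = 1)  # 0.6862915
#' @export
binning_diffusion <- function(T, tauD, r = 1) {
  if (any(T <= 0)) stop("`T` must be > 0")
  if (tauD <= 0) stop("`tauD` must be > 0")
  if (r < 1) stop("`r` must be >= 1")
  alpha <- T / tauD
  beta <- 1 / r^2
  out <- numeric(length(alpha))
  small <- alpha < 0.02
  out[small] <- .gamma_diff_series(alpha[small], beta)
  a <- alpha[!small]
  if (length(a)) {
    if (abs(beta - 1) < 1e-6) {
      out[!small] <- 8 / a^2 * (a / 2 - sqrt(1 + a) + 1)
    } else {
      s <- sqrt(1 + a * beta)
      arg <- sqrt(1 - beta) * (s - 1) / (beta + s - 1)
      if (any(arg <= -1 | arg >= 1))
        stop("artanh argument outside (-1, 1); invalid alpha/beta combination")
      out[!small] <- 4 / (a^2 * beta) *
        (beta * (1 + a) / sqrt(1 - beta) * atanh(arg) - s + 1)
    }
  }
  out
}

#' Isomerization binning function
#'
#' Finite-sampling-time integral of the on/off kernel:
#' `Gamma_iso(T) = 1 + (2/T^2) * F/(1-F) * (tauF*T - tauF^2*(1 - exp(-T/tauF)))`.
#' Tends to `1/(1-F)` as `T -> 0` and to 1 as `T -> Inf`. A series expansion in
#' `x = T/tauF` is used for `x < 1e-3` to avoid cancellation; elsewhere the
#' bracket is computed as `x + expm1(-x)` which is itself cancellation-safe.
#'
#' @param T Sampling time(s), seconds, > 0. Vectorized.
#' @param F Dark-state fraction in `[0, 1)`.
#' @param tauF Relaxation time, seconds.
#' @return Binning factor(s) in `[1, 1/(1-F)]`.
#' @export
binning_isomerization <- function(T, F, tauF) {
  if (any(T <= 0)) stop("`T` must be > 0")
  if (F < 0 || F >= 1) stop("`F` must be in [0, 1)")
  if (tauF <= 0) stop("`tauF` must be > 0")
  x <- T / tauF
  # h(x) = (2/x^2) * (x - (1 - exp(-x))) so that Gamma = 1 + F/(1-F) * h(x)
  h <- numeric(length(x))
  small <- x < 1e-3
  xs <- x[small]
  h[small] <- 1 - xs / 3 + xs^2 / 12 - xs^3 / 60
  xl <- x[!small]
  h[!small] <- 2 / xl^2 * (xl + expm1(-xl))
  1 + F / (1 - F) * h
}

#' Sampling-time-dependent mean single molecule rate model
#'
#' `mu(T) = gamma2 * mu0 * Gamma_diff(T) * Gamma_iso(T)`. With `F = 0` this is
#' the diffusion-only model; its small-T plateau is `gamma2 * mu0`.
#'
#' @param T Sampling time(s), seconds, > 0. Vectorized.
#' @param params A [model_params()].
#' @return Model mSMR value(s), counts/second.
#' @examples
#' p <- model_params(mu0 = 1e5, tauD = 1e-3, r = 1)
#' msmr_model(1e-6, p)  # ~ 1e5 / (2*sqrt(2))
#' @export
msmr_model <- function(T, params) {
  stopifnot(inherits(params, "model_params"))
  g_iso <- if (params$F > 0) binning_isomerization(T, params$F, params$tauF) else 1
  params$gamma2 * params$mu0 * binning_diffusion(T, params$tauD, params$r) * g_iso
}

#' Sampling-time-dependent Mandel Q model
#'
#' `Q(T) = T * mu(T) = gamma2 * mu0 * T * Gamma_diff(T) * Gamma_iso(T)`.
#'
#' @inheritParams msmr_model
#' @return Model Q value(s), dimensionless.
#' @export
q_model <- function(T, params) {
  T * msmr_model(T, params)
}
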