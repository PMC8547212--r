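#' PSF geometry of a 3D Gaussian detection volume
#'
#' The detection volume is modelled as a 3D Gaussian with lateral 1/e^2 radius
#' `r0` and axial 1/e^2 radius `z0`. The derived aspect ratio `r = z0/r0` must
#' be >= 1 (prolate or spherical volumes only); `beta = r0^2/z0^2 = 1/r^2`.
#'
#' @param r0 Lateral 1/e^2 radius, micrometres.
#' @param z0 Axial 1/e^2 radius, micrometres.
#' @return An object of class `psf_geometry` with fields `r0`, `z0`, `r`, `beta`.
#' @examples
#' psf_geometry(r0 = 0.4, z0 = 2.0)
#' @export
psf_geometry <- function(r0, z0) {
  stopifnot(is.numeric(r0), length(r0) == 1L, is.numeric(z0), length(z0) == 1L)
  if (!is.finite(r0) || r0 <= 0) stop("`r0` must be a positive finite number")
  if (!is.finite(z0) || z0 <= 0) stop("`z0` must be a positive finite number")
  r <- z0 / r0
  if (r < 1) stop("axial/lateral ratio z0/r0 = ", format(r), " < 1 is not supported")
  structure(list(r0 = r0, z0 = z0, r = r, beta = 1 / r^2), class = "psf_geometry")
}

#' Physical parameters of the mSMR model
#'
#' Parameter vector of the full sampling-time-dependent mSMR model
#' `mu(T) = gamma2 * mu0 * Gamma_diff(T) * Gamma_iso(T)`.
#'
#' @param mu0 Single-molecule brightness rate at the PSF maximum, counts/second.
#' @param tauD Mean diffusion time through the lateral detection area, seconds.
#' @param r Axial/lateral PSF ratio `z0/r0`, dimensionless, >= 1.
#' @param F Dark-state fraction in `[0, 1)`; 0 disables the isomerization term.
#' @param tauF Isomerization relaxation time `1/(k_on + k_off)`, seconds.
#' @param gamma2 PSF shape factor; `1/(2*sqrt(2))` for a 3D Gaussian.
#' @return An object of class `model_params`.
#' @examples
#' model_params(mu0 = 1e5, tauD = 8e-4, r = 1)
#' @export
model_params <- function(mu0, tauD, r = 1, F = 0, tauF = 1e-5,
                         gamma2 = 1 / (2 * sqrt(2))) {
  for (nm in c("mu0", "tauD", "r", "F", "tauF", "gamma2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a finite numeric scalar")
  }
  if (mu0 <= 0) stop("`mu0` must be > 0")
  if (tauD <= 0) stop("`tauD` must be > 0")
  if (r < 1) stop("`r` must be >= 1")
  if (F < 0 || F >= 1) stop("`F` must be in [0, 1)")
  if (tauF <= 0) stop("`tauF` must be > 0")
  if (gamma2 <= 0 || gamma2 > 1) stop("`gamma2` must be in (0, 1]")
  structure(list(mu0 = mu0, tauD = tauD, r = r, F = F, tauF = tauF,
                 gamma2 = gamma2), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("mSMR model parameters:\n")
  cat(sprintf("  mu0    %g counts/s\n", x$mu0))
  cat(sprintf("  tauD   %g s\n", x$tauD))
  cat(sprintf("  r      %g\n", x$r))
  cat(sprintf("  F      %g\n", x$F))
  cat(sprintf("  tauF   %g s\n", x$tauF))
  cat(sprintf("  gamma2 %g\n", x$gamma2))
  invisible(x)
}

#' Detector artefact parameters
#'
#' @param t_dead Detector dead time, seconds (>= 0).
#' @param p_afterpulse First-order afterpulsing probability, in `[0, 1)`.
#' @param background_rate Background count rate from a blank measurement,
#'   counts/second (>= 0).
#' @return An object of class `detector_params`.
#' @examples
#' detector_params(t_dead = 70e-9, p_afterpulse = 0.006, background_rate = 200)
#' @export
detector_params <- function(t_dead = 0, p_afterpulse = 0, background_rate = 0) {
  stopifnot(is.numeric(t_dead), is.numeric(p_afterpulse), is.numeric(background_rate))
  if (t_dead < 0) stop("`t_dead` must be >= 0")
  if (p_afterpulse < 0 || p_afterpulse >= 1) stop("`p_afterpulse` must be in [0, 1)")
  if (background_rate < 0) stop("`background_rate` must be >= 0")
  structure(list(t_dead = t_dead, p_afterpulse = p_afterpulse,
                 background_rate = background_rate), class = "detector_params")
}
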