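#' A diffusing (or immobile) emitter species
#'
#' @param D Diffusion coefficient, um^2/s, >= 0 (0 = immobile test species).
#' @param count Number of particles of this species in the box.
#' @param mu0 Detected count rate of one particle at the PSF maximum,
#'   counts/second.
#' @return An object of class `sim_species`.
#' @export
sim_species <- function(D, count, mu0) {
  if (D < 0) stop("`D` must be >= 0")
  if (count < 0 || count != round(count)) stop("`count` must be a non-negative integer")
  if (mu0 < 0) stop("`mu0` must be >= 0")
  structure(list(D = D, count = as.integer(count), mu0 = mu0),
            class = "sim_species")
}

#' Monte Carlo simulation configuration
#'
#' The simulation volume is a periodic box spanning `box_multiplier * r0`
#' along x and y and `box_multiplier * z0` along z, centred on the detection
#' volume. The walk step of the fastest species is `max_step_nm`; the common
#' time slice follows from the Einstein-Smoluchowski relation
#' `dt = step^2 / (6 D)` and slower species take shorter steps
#' `sqrt(6 D_i dt)`.
#'
#' @param species A `sim_species` or list of them.
#' @param geometry A [psf_geometry()].
#' @param duration Simulated observation time, seconds.
#' @param box_multiplier Box size in units of `r0` (lateral) and `z0` (axial).
#' @param max_step_nm Maximum lattice step, nanometres (<= 20 to stay in the
#'   Wiener-process regime).
#' @param output_bin_width Requested trace bin width, seconds; rounded to the
#'   nearest positive integer multiple of the time slice.
#' @param seed Integer RNG seed; identical seed + config gives a bit-identical
#'   trace.
#' @param delta_t Optional explicit time slice, seconds; required when all
#'   species are immobile (no `D > 0` to set the clock).
#' @param blinking Optional list `list(k_on = , k_off = )`, 1/s, enabling
#'   two-state on/off emission (dark fraction `F = k_off/(k_on+k_off)`,
#'   relaxation time `tauF = 1/(k_on+k_off)`).
#' @param init_positions Optional 3 x P matrix of starting positions (um);
#'   default uniform in the box, the stationary density under periodic
#'   boundaries.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(species, geometry, duration,
                       box_multiplier = 12, max_step_nm = 20,
                       output_bin_width = 1e-6, seed = 1L,
                       delta_t = NULL, blinking = NULL,
                       init_positions = NULL) {
  if (inherits(species, "sim_species")) species <- list(species)
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, logical(1), "sim_species")),
            inherits(geometry, "psf_geometry"))
  if (duration <= 0) stop("`duration` must be > 0")
  if (max_step_nm <= 0 || max_step_nm > 20)
    stop("`max_step_nm` must be in (0, 20] nm")
  if (!is.null(blinking)) {
    stopifnot(is.list(blinking), all(c("k_on", "k_off") %in% names(blinking)))
    if (blinking$k_on <= 0 || blinking$k_off < 0) stop("invalid blinking rates")
  }
  structure(list(species = species, geometry = geometry, duration = duration,
                 box_multiplier = box_multiplier, max_step_nm = max_step_nm,
                 output_bin_width = output_bin_width, seed = as.integer(seed),
                 delta_t = delta_t, blinking = blinking,
                 init_positions = init_positions),
            class = "sim_config")
}

#' Time slice and per-species step sizes
#'
#' `dt = step_max^2 / (6 D_fastest)`; species step `sqrt(6 D_i dt)`, so the
#' fastest species moves exactly `max_step_nm` and all others less. When every
#' species is immobile the configured `delta_t` is used and all steps are 0.
#'
#' @param config A [sim_config()].
#' @return List with `delta_t` (seconds) and `step_um` (per-species, um).
#' @examples
#' cfg <- sim_config(sim_species(D = 50, count = 20, mu0 = 1e5),
#'                   psf_geometry(0.4, 0.4), duration = 1)
#' time_slice(cfg)  # dt = 1.333e-6 s, step 0.02 um
#' @export
time_slice <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  Ds <- vapply(config$species, `[[`, numeric(1), "D")
  eps <- config$max_step_nm * 1e-3  # um
  if (all(Ds == 0)) {
    if (is.null(config$delta_t))
      stop("no diffusing species: supply an explicit `delta_t`")
    return(list(delta_t = config$delta_t, step_um = Ds))
  }
  dt <- eps^2 / (6 * max(Ds))
  list(delta_t = dt, step_um = sqrt(6 * Ds * dt))
}

#' Normalized 3D Gaussian PSF value
#'
#' `exp(-2 (x^2 + y^2)/r0^2 - 2 z^2/z0^2)`; 1 at the origin.
#'
#' @param position Numeric 3-vector (x, y, z), micrometres, or a 3 x n matrix.
#' @param geometry A [psf_geometry()].
#' @return Value(s) in `[0, 1]`.
#' @export
psf_value <- function(position, geometry) {
  stopifnot(inherits(geometry, "psf_geometry"))
  p <- if (is.matrix(position)) position else matrix(position, nrow = 3)
  if (nrow(p) != 3) stop("`position` must have 3 coordinates")
  exp(-2 * (p[1, ]^2 + p[2, ]^2) / geometry$r0^2 - 2 * p[3, ]^2 / geometry$z0^2)
}

#' Simulate a photon trace
#'
#' Runs the lattice-walk Monte Carlo: particles start uniformly in the
#' periodic box, each time slice they jump one step along a uniformly chosen
#' axis direction, and photon emission is Poissonian with per-particle
#' intensity `mu0 * dt * PSF(r)`. Slice counts are summed into output bins of
#' width `output_bin_width` rounded to an integer multiple of the slice.
#'
#' @param config A [sim_config()].
#' @return A [photon_trace()]; the realized bin width is in the returned
#'   object and the slice bookkeeping in its attributes (`delta_t`, `agg`).
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ts <- time_slice(config)
  dt <- ts$delta_t
  agg <- max(1L, as.integer(round(config$output_bin_width / dt)))
  bin_width <- agg * dt
  # tolerant floor: duration/bin_width is meant to be integral for round
  # durations, but bin_width carries rounding from eps^2/(6D)
  n_out <- floor(config$duration / bin_width + 1e-6)
  if (n_out * agg < 1000)
    stop("duration too short: fewer than 1000 time slices")
  geom <- config$geometry
  half_x <- config$box_multiplier * geom$r0 / 2
  half_z <- config$box_multiplier * geom$z0 / 2

  counts_per <- vapply(config$species, `[[`, numeric(1), "count")
  P <- sum(counts_per)
  if (P == 0) stop("no particles configured")
  sp_idx <- rep(seq_along(config$species), counts_per)
  step <- ts$step_um[sp_idx]
  phi0 <- vapply(config$species, `[[`, numeric(1), "mu0")[sp_idx] * dt

  set.seed(config$seed)
  if (is.null(config$init_positions)) {
    pos <- rbind(stats::runif(P, -half_x, half_x),
                 stats::runif(P, -half_x, half_x),
                 stats::runif(P, -half_z, half_z))
  } else {
    pos <- config$init_positions
    stopifnot(is.matrix(pos), nrow(pos) == 3, ncol(pos) == P)
  }
  if (is.null(config$blinking)) {
    bright <- rep(TRUE, P)
    p_dark <- p_bright <- 0
  } else {
    k_on <- config$blinking$k_on
    k_off <- config$blinking$k_off
    F_dark <- k_off / (k_on + k_off)
    bright <- stats::runif(P) >= F_dark
    p_dark <- k_off * dt
    p_bright <- k_on * dt
    if (p_dark > 0.1 || p_bright > 0.1)
      stop("blinking rates too fast for the time slice (k*dt > 0.1)")
  }

  counts <- .sim_lattice_trace(n_out, agg, pos, step, phi0,
                               geom$r0, geom$z0, half_x, half_z,
                               bright, p_dark, p_bright)
  tr <- photon_trace(counts, bin_width)
  attr(tr, "delta_t") <- dt
  attr(tr, "agg") <- agg
  tr
}

#' Analytic box-average of the PSF
#'
#' Mean of the normalized 3D Gaussian over the periodic simulation box; the
#' long-run mean counts per slice of the simulator is
#' `sum(count_i * mu0_i * dt) * psf_box_average(...)`.
#'
#' @param geometry A [psf_geometry()].
#' @param box_multiplier Box size in units of `r0`/`z0`.
#' @return Dimensionless mean in (0, 1).
#' @export
psf_box_average <- function(geometry, box_multiplier = 12) {
  m <- box_multiplier
  # separable: mean of exp(-2 u^2 / w^2) over [-m w/2, m w/2] is
  # sqrt(pi/2) * erf(m / sqrt(2)) / m per axis (the width w cancels)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  (sqrt(pi / 2) * erf(m / sqrt(2)) / m)^3
}
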