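#' Correct measured moments for afterpulsing and dead time
#'
#' First-order correction of the measured photocount moments at sampling time
#' `T`:
#' `<k>   = <k>_m (1 - P_A - delta) + delta <k^2>_m`
#' `<k^2> = <k^2>_m (1 - 2 P_A - 3 delta) + 2 delta <k^3>_m + (delta - P_A) <k>_m`
#' with `delta = t_dead / T` the dimensionless dead time. Valid only while
#' `<k> * delta << 1`; this function warns above 0.1 and errors above 0.5.
#' With `P_A = delta = 0` both moments pass through unchanged.
#'
#' @param m1,m2,m3 Measured first, second and third raw moments at `T`.
#' @param T Sampling time, seconds, > 0.
#' @param det A [detector_params()].
#' @return Named numeric vector `c(m1, m2)` of corrected moments.
#' @examples
#' correct_moments(1, 2, 5, T = 1e-5,
#'                 detector_params(t_dead = 7e-8, p_afterpulse = 0.01))
#' @export
correct_moments <- function(m1, m2, m3, T, det) {
  stopifnot(inherits(det, "detector_params"))
  if (T <= 0) stop("`T` must be > 0")
  delta <- det$t_dead / T
  pa <- det$p_afterpulse
  v <- m1 * delta
  if (v > 0.5)
    stop(sprintf("dead-time correction invalid at T = %g s: <k>*delta = %.3g > 0.5", T, v))
  if (v > 0.1)
    warning(sprintf("dead-time correction marginal at T = %g s: <k>*delta = %.3g > 0.1", T, v))
  c(m1 = m1 * (1 - pa - delta) + delta * m2,
    m2 = m2 * (1 - 2 * pa - 3 * delta) + 2 * delta * m3 + (delta - pa) * m1)
}

#' Background correction factor chi-squared
#'
#' `chi^2 = (1 + b/(k - b))^2` for mean counts per bin `k` and mean background
#' counts per bin `b`; the classic particle-number correction for a reduced
#' signal-to-noise ratio. Equals 1 for `b = 0`.
#'
#' @param mean_counts Mean measured counts per bin, `k > b`.
#' @param background_counts Mean background counts per bin, `b >= 0`.
#' @return Dimensionless factor >= 1.
#' @export
background_chi2 <- function(mean_counts, background_counts) {
  if (background_counts < 0) stop("background must be >= 0")
  if (background_counts >= mean_counts)
    stop("background correction undefined: background >= signal")
  (1 + background_counts / (mean_counts - background_counts))^2
}

#' Background-correct a fitted brightness rate
#'
#' `mu0_corr = mu0 / (1 - b/k)`: the brightness underestimate caused by a
#' Poissonian background of mean `b` counts per bin on a signal of `k` counts
#' per bin.
#'
#' @param mu0_measured Fitted brightness rate, counts/second.
#' @param mean_counts Mean measured counts per bin.
#' @param background_counts Mean background counts per bin, `< mean_counts`.
#' @return Corrected brightness rate, counts/second, >= input.
#' @examples
#' background_correct_mu0(1e5, mean_counts = 1, background_counts = 0.1)
#' @export
background_correct_mu0 <- function(mu0_measured, mean_counts, background_counts) {
  if (background_counts < 0) stop("background must be >= 0")
  if (background_counts >= mean_counts)
    stop("background correction undefined: background >= signal")
  mu0_measured / (1 - background_counts / mean_counts)
}

#' Background-correct an mSMR curve
#'
#' Multiplies every `mu(T)` (and `Q(T)`) by `(1 - <b>/<k>)^-1` with
#' `<b> = background_rate * T`. For a stationary trace `<k>` is exactly
#' proportional to `T`, so the ratio `<b>/<k>` — and hence the scale factor —
#' is a single constant across the curve; this is asserted to 1e-9 relative.
#'
#' @param curve An `msmr_curve`.
#' @param background_rate Background count rate from a blank, counts/second.
#' @return The corrected `msmr_curve` with `corr_background = TRUE`.
#' @export
background_correct_curve <- function(curve, background_rate) {
  stopifnot(inherits(curve, "msmr_curve"))
  if (background_rate < 0) stop("`background_rate` must be >= 0")
  if (background_rate == 0) return(curve)
  ratio <- background_rate * curve$T_s / curve$m1
  if (any(ratio >= 1))
    stop("background correction undefined: background exceeds signal at T = ",
         format(curve$T_s[which(ratio >= 1)[1]]))
  if (diff(range(ratio)) > 1e-9 * mean(ratio))
    stop("background/signal ratio varies across sampling times; trace not stationary")
  fac <- 1 / (1 - ratio[1])
  curve$Q <- curve$Q * fac
  curve$mu_cps <- curve$mu_cps * fac
  curve$corr_background <- TRUE
  curve
}

# ---- synthetic artefact injection (test instrumentation) --------------------
# The corrections above undo artefacts; these create them, so that correction
# direction and magnitude can be exercised on traces with known ground truth.

#' Inject detector dead time into a trace
#'
#' Nonparalyzable dead-time clipping at trace resolution: the k events of each
#' bin are given uniform arrival times inside the bin, sorted, and every event
#' closer than `t_dead` to the previously retained one is removed. Stochastic;
#' seed via [set.seed()].
#'
#' @param trace A [photon_trace()]; bin width should be >> `t_dead`.
#' @param t_dead Dead time, seconds.
#' @return A clipped [photon_trace()].
#' @export
inject_dead_time <- function(trace, t_dead) {
  stopifnot(inherits(trace, "photon_trace"), t_dead >= 0)
  if (t_dead == 0) return(trace)
  counts <- vapply(trace$counts, function(k) {
    if (k <= 1) return(k)
    tt <- sort(stats::runif(k, 0, trace$bin_width))
    kept <- 1L
    last <- tt[1]
    for (i in 2:k) {
      if (tt[i] - last >= t_dead) {
        kept <- kept + 1L
        last <- tt[i]
      }
    }
    as.numeric(kept)
  }, numeric(1))
  photon_trace(counts, trace$bin_width, trace$origin_time)
}

#' Inject first-order afterpulsing into a trace
#'
#' Each detected count triggers one spurious extra count in the same bin with
#' probability `p_afterpulse` (afterpulse delays are ns-scale, far below any
#' bin width used here). Stochastic; seed via [set.seed()].
#'
#' @param trace A [photon_trace()].
#' @param p_afterpulse Afterpulsing probability in `[0, 1)`.
#' @return A [photon_trace()] with extra counts.
#' @export
inject_afterpulsing <- function(trace, p_afterpulse) {
  stopifnot(inherits(trace, "photon_trace"),
            p_afterpulse >= 0, p_afterpulse < 1)
  if (p_afterpulse == 0) return(trace)
  extra <- stats::rbinom(length(trace$counts), size = trace$counts, prob = p_afterpulse)
  photon_trace(trace$counts + extra, trace$bin_width, trace$origin_time)
}

#' Inject uniform Poisson background into a trace
#'
#' Adds i.i.d. Poisson(`rate * bin_width`) counts per bin, emulating detector
#' dark counts or uncorrelated stray light. Stochastic; seed via [set.seed()].
#'
#' @param trace A [photon_trace()].
#' @param rate Background count rate, counts/second.
#' @return A [photon_trace()] with background added.
#' @export
inject_background <- function(trace, rate) {
  stopifnot(inherits(trace, "photon_trace"), rate >= 0)
  if (rate == 0) return(trace)
  bg <- stats::rpois(length(trace$counts), rate * trace$bin_width)
  photon_trace(trace$counts + bg, trace$bin_width, trace$origin_time)
}
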