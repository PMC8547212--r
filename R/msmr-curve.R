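#' Empirical mSMR curve from a photon trace
#'
#' Rebins the trace at every integer-divisor sampling time `T` up to
#' `t_max_fraction * T_obs`, computes the measured raw moments at each `T`,
#' optionally corrects them for detector dead time and afterpulsing, and
#' evaluates `Q(T)` and the mean single molecule rate `mu(T) = Q(T)/T`.
#'
#' The default cutoff keeps at least 100 bins per sampling time
#' (`t_max_fraction = 0.01`): with fewer bins the variance of the second-moment
#' estimator dominates. Entries with zero mean counts are dropped. Background
#' is not handled here; see [background_correct_curve()].
#'
#' @param trace A [photon_trace()].
#' @param t_max_fraction Largest sampling time as a fraction of the total
#'   observation time, in (0, 1].
#' @param corrections Optional [detector_params()]; when given, measured
#'   moments are corrected for dead time and afterpulsing before Q.
#' @return A data.frame of class `msmr_curve` with columns `T_s`, `m1`, `m2`,
#'   `m3`, `n_bins`, `Q`, `mu_cps`, `corr_deadtime`, `corr_afterpulse`,
#'   `corr_background`, ordered by increasing `T_s`; the trace bin width and
#'   total observation time are kept as attributes.
#' @examples
#' tr <- photon_trace(rpois(4000, 2), bin_width = 1e-6)
#' head(msmr_curve(tr, t_max_fraction = 0.05))
#' @export
msmr_curve <- function(trace, t_max_fraction = 0.01, corrections = NULL) {
  stopifnot(inherits(trace, "photon_trace"))
  if (t_max_fraction <= 0 || t_max_fraction > 1)
    stop("`t_max_fraction` must be in (0, 1]")
  if (!is.null(corrections)) stopifnot(inherits(corrections, "detector_params"))
  n <- length(trace$counts)
  T_obs <- n * trace$bin_width
  factors <- integer_divisors(n)
  factors <- factors[factors * trace$bin_width <= t_max_fraction * T_obs]
  if (length(factors) == 0L) stop("no divisor sampling time below the cutoff")

  apply_det <- !is.null(corrections) &&
    (corrections$t_dead > 0 || corrections$p_afterpulse > 0)
  rows <- lapply(factors, function(f) {
    rb <- rebin(trace, f)
    m <- raw_moments(rb)
    T_s <- rb$bin_width
    if (m[["m1"]] == 0) return(NULL)  # empty segment: drop, never impute
    if (apply_det) {
      cm <- correct_moments(m[["m1"]], m[["m2"]], m[["m3"]], T_s, corrections)
      q <- mandel_q(cm[["m1"]], cm[["m2"]])
    } else {
      q <- mandel_q(m[["m1"]], m[["m2"]])
    }
    data.frame(T_s = T_s, m1 = m[["m1"]], m2 = m[["m2"]], m3 = m[["m3"]],
               n_bins = length(rb$counts), Q = q, mu_cps = q / T_s,
               corr_deadtime = apply_det && corrections$t_dead > 0,
               corr_afterpulse = apply_det && corrections$p_afterpulse > 0,
               corr_background = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 4L)
    stop("insufficient data: fewer than 4 valid sampling times")
  out <- do.call(rbind, rows)
  out <- out[order(out$T_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("msmr_curve", "data.frame"),
            bin_width = trace$bin_width, T_obs = T_obs)
}

# keep class/attributes when subsetting rows would otherwise drop them
#' @export
`[.msmr_curve` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "bin_width") <- attr(x, "bin_width")
    attr(out, "T_obs") <- attr(x, "T_obs")
    class(out) <- c("msmr_curve", "data.frame")
  }
  out
}

#' Average several mSMR curves point-by-point
#'
#' Curves must share an identical sampling-time grid (replicate runs of the
#' same protocol). Moments, Q and mu are averaged arithmetically per `T`.
#'
#' @param curves List of `msmr_curve` objects on one grid.
#' @return An `msmr_curve` of the same shape.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1L, all(vapply(curves, inherits, logical(1), "msmr_curve")))
  grid <- curves[[1]]$T_s
  for (cv in curves) {
    if (length(cv$T_s) != length(grid) || any(cv$T_s != grid))
      stop("curves are not on an identical sampling-time grid")
  }
  out <- curves[[1]]
  for (col in c("m1", "m2", "m3", "Q", "mu_cps")) {
    out[[col]] <- rowMeans(vapply(curves, function(cv) cv[[col]],
                                  numeric(length(grid))))
  }
  out
}
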