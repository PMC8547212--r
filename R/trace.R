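#' Construct a binned photon-count trace
#'
#' The raw observable: one non-negative integer photon count per equal-width
#' time bin. `bin_width` is the minimum sampling time of the measurement.
#'
#' @param counts Integer vector of non-negative counts, length >= 2.
#' @param bin_width Bin width, seconds, > 0.
#' @param origin_time Start time of the first bin, seconds.
#' @return An object of class `photon_trace`.
#' @examples
#' photon_trace(c(2L, 0L, 1L, 3L), bin_width = 1e-6)
#' @export
photon_trace <- function(counts, bin_width, origin_time = 0) {
  if (!is.numeric(counts) || length(counts) < 2L)
    stop("`counts` must be a numeric vector of length >= 2")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a positive scalar, seconds")
  structure(list(counts = as.numeric(counts), bin_width = bin_width,
                 origin_time = origin_time), class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf("photon trace: %d bins of %g s (T_obs = %g s), %s counts, mean rate %g cps\n",
              n, x$bin_width, n * x$bin_width,
              format(sum(x$counts), big.mark = ","),
              sum(x$counts) / (n * x$bin_width)))
  invisible(x)
}

#' @export
length.photon_trace <- function(x) length(x$counts)

#' All integer divisors of n
#'
#' Every rebinning factor that tiles a trace of length `n` exactly; ascending,
#' always includes 1 and `n`.
#'
#' @param n Positive integer.
#' @return Sorted integer vector of divisors.
#' @examples
#' integer_divisors(12)  # 1 2 3 4 6 12
#' @export
integer_divisors <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  small <- seq_len(floor(sqrt(n)))
  small <- small[n %% small == 0]
  sort(unique(c(small, n %/% small)))
}

#' Rebin a photon trace by an integer factor
#'
#' Sums each block of `factor` consecutive bins into one output bin; the bin
#' width multiplies by `factor` and total counts are conserved exactly. The
#' factor must divide the trace length: no silent truncation.
#'
#' @param trace A [photon_trace()].
#' @param factor Positive integer dividing `length(trace)`.
#' @return A [photon_trace()] of length `n/factor`.
#' @examples
#' rebin(photon_trace(c(1, 2, 3, 4), 1e-6), 2)$counts  # 3 7
#' @export
rebin <- function(trace, factor) {
  stopifnot(inherits(trace, "photon_trace"))
  n <- length(trace$counts)
  if (factor < 1 || factor != round(factor))
    stop("`factor` must be a positive integer")
  if (n %% factor != 0)
    stop("rebinning factor ", factor, " does not divide trace length ", n)
  counts <- if (factor == 1) trace$counts else
    .colSums(trace$counts, factor, n %/% factor)
  structure(list(counts = counts, bin_width = trace$bin_width * factor,
                 origin_time = trace$origin_time), class = "photon_trace")
}

#' Raw moments of a photon trace
#'
#' `m_j = (1/n) * sum(k_i^j)` for j = 1..3. Counts and their powers are exact
#' integers in double precision well past any realistic trace, so sums are
#' exact before the final division.
#'
#' @param trace A [photon_trace()] (or bare numeric vector of counts).
#' @return Named numeric vector `c(m1, m2, m3)`.
#' @examples
#' raw_moments(photon_trace(c(2, 0, 1, 3), 1))  # 1.5 3.5 9.0
#' @export
raw_moments <- function(trace) {
  k <- if (inherits(trace, "photon_trace")) trace$counts else trace
  if (length(k) == 0L) stop("empty trace")
  n <- length(k)
  c(m1 = sum(k) / n, m2 = sum(k^2) / n, m3 = sum(k^3) / n)
}

#' Mandel Q parameter from raw moments
#'
#' `Q = (<k^2> - <k>^2 - <k>) / <k>`: 0 for Poisson statistics, positive for
#' superpoissonian light (e.g. diffusing emitters), negative for
#' subpoissonian.
#'
#' @param m1 Mean counts per bin, > 0.
#' @param m2 Mean squared counts per bin.
#' @return Dimensionless Q; `NA_real_` (with a warning) when `m1 = 0`.
#' @examples
#' mandel_q(1.5, 3.5)  # -1/6
#' @export
mandel_q <- function(m1, m2) {
  if (m1 == 0) {
    warning("Q undefined for zero mean counts")
    return(NA_real_)
  }
  (m2 - m1^2 - m1) / m1
}

#' Bin photon arrival timestamps into a trace
#'
#' Half-open bins `[t, t + bin_width)` starting at `origin_time`. Events at or
#' beyond `origin_time + n_bins * bin_width` are dropped with a warning.
#'
#' @param timestamps Sorted arrival times, seconds.
#' @param bin_width Bin width, seconds.
#' @param duration Total observation time, seconds; defaults to the span
#'   rounded down to a whole number of bins.
#' @param origin_time Start of the first bin, seconds.
#' @return A [photon_trace()].
#' @export
bin_timestamps <- function(timestamps, bin_width, duration = NULL, origin_time = 0) {
  if (is.unsorted(timestamps)) stop("`timestamps` must be sorted ascending")
  if (is.null(duration)) {
    n_bins <- max(2L, floor((max(timestamps) - origin_time) / bin_width))
  } else {
    n_bins <- floor(duration / bin_width)
  }
  idx <- floor((timestamps - origin_time) / bin_width) + 1
  if (any(idx < 1)) stop("timestamps before `origin_time`")
  dropped <- sum(idx > n_bins)
  if (dropped > 0) {
    warning(dropped, " event(s) at or beyond the observation window dropped")
    idx <- idx[idx <= n_bins]
  }
  counts <- tabulate(idx, nbins = n_bins)
  photon_trace(counts, bin_width, origin_time)
}
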