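.FIT_BOUNDS <- list(
  mu0  = c(1e-9, 1e9),
  tauD = c(1e-7, 10),
  r    = c(1, 100),
  F    = c(0, 0.99),
  tauF = c(1e-8, 1e-2)
)

#' Automatic starting values for an mSMR fit
#'
#' Plateau of the positive part of the curve gives `mu0 = max(mu)/gamma2`;
#' `tauD` is the sampling time at the half-plateau crossing, interpolated in
#' log T (largest T as fallback when the curve never decays that far);
#' `F = 0.1` and `tauF` one decade below the `tauD` guess.
#'
#' @param curve An `msmr_curve` with >= 4 valid points.
#' @param r Axial/lateral ratio to embed in the guess.
#' @return A [model_params()].
#' @export
initial_guess <- function(curve, r = 1) {
  stopifnot(inherits(curve, "msmr_curve"))
  pos <- curve[curve$mu_cps > 0, , drop = FALSE]
  if (nrow(pos) < 4L) stop("need >= 4 positive mSMR points for a starting guess")
  gamma2 <- 1 / (2 * sqrt(2))
  plateau <- max(pos$mu_cps)
  mu0 <- plateau / gamma2
  below <- which(pos$mu_cps < plateau / 2)
  if (length(below) == 0L) {
    tauD <- max(pos$T_s)  # curve never decays to half: boundary fallback
  } else {
    j <- below[1]
    if (j == 1L) {
      tauD <- pos$T_s[1]
    } else {
      # log-T interpolation between the bracketing points
      f <- (pos$mu_cps[j - 1] - plateau / 2) / (pos$mu_cps[j - 1] - pos$mu_cps[j])
      tauD <- exp((1 - f) * log(pos$T_s[j - 1]) + f * log(pos$T_s[j]))
    }
  }
  tauD <- min(max(tauD, .FIT_BOUNDS$tauD[1]), .FIT_BOUNDS$tauD[2])
  tauF <- min(max(tauD / 10, .FIT_BOUNDS$tauF[1]), .FIT_BOUNDS$tauF[2])
  model_params(mu0 = mu0, tauD = tauD, r = r, F = 0.1, tauF = tauF)
}

#' Fit the mSMR model to an empirical curve
#'
#' Levenberg-Marquardt least squares of `mu(T) = gamma2 mu0 Gamma_diff(T)`
#' (optionally times `Gamma_iso(T)` when `include_iso = TRUE`) against the
#' curve's `(T, mu)` points, minimizing `sum w_i (mu_i - model(T_i))^2`.
#'
#' `r` is fixed by default and should come from an independent calibration:
#' above `r ~ 3` the model is nearly insensitive to it, so leaving it free is
#' ill-conditioned (a warning is issued). Non-convergence is reported via the
#' `converged` flag, not an error.
#'
#' @param curve An `msmr_curve`.
#' @param initial Optional [model_params()] starting point; derived via
#'   [initial_guess()] when absent.
#' @param fixed Character vector of parameter names to hold at their initial
#'   values (subset of mu0, tauD, r, F, tauF). `r` is always sensible to fix.
#' @param include_iso Fit the on/off isomerization term? When `FALSE`, `F`
#'   and `tauF` are fixed at `F = 0`.
#' @param weights Optional per-point weights (default: unweighted).
#' @return An object of class `fit_result`: fitted [model_params()],
#'   covariance-derived `std_errors` (NA for fixed parameters),
#'   `fixed_mask`, `residual_norm`, `n_points`, `converged`, `info`.
#' @export
fit_msmr <- function(curve, initial = NULL, fixed = "r",
                     include_iso = FALSE, weights = NULL) {
  stopifnot(inherits(curve, "msmr_curve"))
  if (all(curve$mu_cps <= 0)) stop("unfittable curve: all mSMR values <= 0")
  if (is.null(initial)) initial <- initial_guess(curve)
  stopifnot(inherits(initial, "model_params"))
  all_names <- c("mu0", "tauD", "r", "F", "tauF")
  if (!all(fixed %in% all_names)) stop("unknown parameter name in `fixed`")
  if (!include_iso) {
    fixed <- union(fixed, c("F", "tauF"))
    initial$F <- 0
  }
  free <- setdiff(all_names, fixed)
  if ("r" %in% free && initial$r > 3)
    warning("`r` left free above 3: the model is insensitive to r there; ",
            "fix it from a calibration measurement")
  n_pts <- nrow(curve)
  if (n_pts < length(free) + 1L)
    stop("curve has fewer points than free parameters + 1")
  w <- if (is.null(weights)) rep(1, n_pts) else {
    stopifnot(length(weights) == n_pts, all(weights >= 0))
    weights
  }
  sw <- sqrt(w)
  Tv <- curve$T_s
  mu <- curve$mu_cps

  start <- unlist(initial[free])
  lower <- vapply(free, function(p) .FIT_BOUNDS[[p]][1], numeric(1))
  upper <- vapply(free, function(p) .FIT_BOUNDS[[p]][2], numeric(1))
  start <- pmin(pmax(start, lower), upper)
  build <- function(par) {
    p <- initial
    p[free] <- as.list(par)
    p
  }
  resid_fn <- function(par) {
    p <- build(par)
    sw * (mu - msmr_model(Tv, p))
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, maxfev = 10000, maxiter = 1024))
  converged <- fit$info %in% 1:3
  pars <- build(fit$par)
  dof <- n_pts - length(free)
  se <- rep(NA_real_, length(all_names))
  names(se) <- all_names
  cov_try <- try({
    s2 <- fit$deviance / max(dof, 1L)
    # pre-scale: parameter magnitudes span ~10 decades, raw J'J is numerically
    # singular even for well-posed fits
    d <- sqrt(diag(fit$hessian))
    Hs <- fit$hessian / outer(d, d)
    sqrt(pmax(s2 * diag(solve(Hs)) / d^2, 0))
  }, silent = TRUE)
  if (!inherits(cov_try, "try-error")) se[free] <- cov_try
  structure(list(params = pars, std_errors = se,
                 fixed_mask = all_names %in% fixed,
                 residual_norm = fit$deviance, n_points = n_pts,
                 converged = converged, info = fit$info,
                 message = fit$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("mSMR fit (%s, %d points, SSR = %.4g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$residual_norm))
  nm <- c("mu0", "tauD", "r", "F", "tauF")
  for (i in seq_along(nm)) {
    fx <- if (x$fixed_mask[i]) " (fixed)" else
      sprintf(" +- %.3g", x$std_errors[nm[i]])
    cat(sprintf("  %-5s %.6g%s\n", nm[i], x$params[[nm[i]]], fx))
  }
  invisible(x)
}

#' Diffusion coefficient from the fitted diffusion time
#'
#' `D = r0^2 / (4 tauD)` with the lateral 1/e^2 radius `r0` from a
#' calibration measurement.
#'
#' @param tauD Mean diffusion time, seconds.
#' @param r0 Lateral radius, micrometres.
#' @return Diffusion coefficient, um^2/s.
#' @examples
#' diffusion_coefficient(8e-4, 0.4)  # 50
#' @export
diffusion_coefficient <- function(tauD, r0) {
  if (tauD <= 0) stop("`tauD` must be > 0")
  if (r0 <= 0) stop("`r0` must be > 0")
  r0^2 / (4 * tauD)
}

#' Aggregate replicate fit results
#'
#' Per-parameter arithmetic mean and sample standard deviation over the
#' converged replicates (the convention for repeated measurements of one
#' well/condition). Non-converged replicates are excluded and counted.
#'
#' @param results List of `fit_result` objects with identical `fixed_mask`.
#' @return List with `mean`, `sd` (named over free parameters),
#'   `n_used`, `n_excluded`.
#' @export
aggregate_fits <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "fit_result")))
  masks <- vapply(results, function(r) paste(r$fixed_mask, collapse = ""), "")
  if (length(unique(masks)) != 1L)
    stop("fit results have different fixed-parameter masks")
  ok <- vapply(results, `[[`, logical(1), "converged")
  if (!any(ok)) stop("no converged fits to aggregate")
  if (sum(ok) < 2L) stop("need >= 2 converged fits to aggregate")
  use <- results[ok]
  free <- c("mu0", "tauD", "r", "F", "tauF")[!use[[1]]$fixed_mask]
  vals <- vapply(use, function(r) unlist(r$params[free]), numeric(length(free)))
  vals <- matrix(vals, nrow = length(free), dimnames = list(free, NULL))
  list(mean = rowMeans(vals), sd = apply(vals, 1, stats::sd),
       n_used = sum(ok), n_excluded = sum(!ok))
}
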