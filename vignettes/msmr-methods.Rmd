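---
title: "Mean single molecule rate analysis: models, estimator, and Monte Carlo validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean single molecule rate analysis: models, estimator, and Monte Carlo validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmr)
```

## The method

Fluorescence fluctuation spectroscopy (FFS) extracts single-molecule
properties from the intensity fluctuations produced by fluorescent particles
diffusing through a small, confocally illuminated detection volume. This
package implements an analysis built on Mandel's Q parameter of the binned
photon counts,

$$Q = \frac{\langle k^2\rangle - \langle k\rangle^2 - \langle k\rangle}
           {\langle k\rangle},$$

which is zero for Poisson light, positive (superpoissonian) for fluctuating
molecular signals, and negative (subpoissonian) for clipped ones. Q depends
on the width $T$ of the counting bins. Its ratio to $T$,

$$\mu(T) = \frac{Q(T)}{T} = \gamma_2\,\mu_0\,
  \Gamma_{\mathrm{diff}}(T)\,\Gamma_{\mathrm{iso}}(T),$$

is the *mean single molecule rate* (mSMR). Its small-$T$ plateau is
$\gamma_2 \mu_0$ — the single-molecule brightness rate $\mu_0$ (counts/s of
one molecule at the detection-volume maximum) scaled by the PSF shape factor
$\gamma_2 = 1/(2\sqrt 2)$ of a 3D Gaussian volume — and its decay with $T$
encodes the diffusion time. Unlike an FCS amplitude, $\mu(T)$ is independent
of concentration, which is what makes it attractive for, e.g., DNA
quantification assays where brightness per molecule is the analyte property.

### The binning functions

The finite sampling time enters through the *binning function* of a
correlation kernel $g$,

$$\Gamma(T) = \frac{2}{T^2}\int_0^T (T-\tau)\, g(\tau)\,\mathrm d\tau .$$

For free 3D diffusion through a Gaussian volume with lateral radius $r_0$,
axial radius $z_0$, aspect ratio $r = z_0/r_0 \ge 1$ and
$\beta = 1/r^2$, the kernel is
$g(\tau) = [(1+\tau/\tau_D)\sqrt{1+\beta\,\tau/\tau_D}]^{-1}$ and
$\Gamma_{\mathrm{diff}}$ has a closed form with two branches
(`binning_diffusion()`): an elementary one at $r = 1$ and an
$\operatorname{artanh}$ form for $r > 1$, in the dimensionless sampling time
$\alpha = T/\tau_D$. Dark-state blinking (cis/trans isomerization of cyanine
dyes, the dominant photokinetic effect for the DNA stains this method
targets) contributes a second kernel
$g_{\mathrm{iso}}(t) = 1 + \frac{F}{1-F}e^{-t/\tau_F}$ with dark fraction
$F$ and relaxation time $\tau_F = 1/(k_{\mathrm{on}}+k_{\mathrm{off}})$,
whose binning function `binning_isomerization()` interpolates between
$1/(1-F)$ at $T \to 0$ and 1 at $T \to \infty$.

### Numerical choices

Both closed forms lose essentially all significant digits to cancellation at
small $\alpha$ (the interesting quantity is an $O(\alpha^2)$ difference of
$O(1)$ terms). We therefore switch to Taylor series below $\alpha = 0.02$
(diffusion; terms through $\alpha^4$, valid for any $\beta$, so one series
serves both branches) and below $T/\tau_F = 10^{-3}$ (isomerization; the
non-series branch additionally uses `expm1` so the only remaining
subtraction is benign). At the switch points both sides agree to better than
$10^{-9}$ relative, and the closed forms agree with adaptive quadrature of
the defining integral to $10^{-8}$ over $\alpha \in [10^{-3}, 10^{3}]$ —
this is asserted by the test suite. The $r=1$ branch is used whenever
$|\beta - 1| < 10^{-6}$ because the $r>1$ branch is a 0/0 limit there; an
$\operatorname{artanh}$ argument outside $(-1,1)$ raises an error rather
than being clamped. Note that the two branches are *mathematically* distinct
functions of $\beta$: at $r = 1 + 10^{-5}$ they genuinely differ by a few
$10^{-6}$ at large $\alpha$, which is model sensitivity, not numerical
error.

## The estimator

`msmr_curve()` turns a binned photon trace of length $n$ into an empirical
mSMR curve by rebinning at **every integer divisor** of $n$ (exact block
sums, total counts conserved), computing the raw moments
$\langle k\rangle, \langle k^2\rangle, \langle k^3\rangle$ at each sampling
time, and forming $Q(T)$ and $\mu(T) = Q(T)/T$. Counts and their cubes are
integers represented exactly in double precision for any realistic trace,
so the accumulation is exact before the final division. Two conventions the
method's description leaves open were fixed as follows:

* **Maximum sampling time.** By default only sampling times with at least
  100 contributing bins are kept (`t_max_fraction = 0.01`): the variance of
  the second-moment estimator grows rapidly below that, and those points
  would destabilize an unweighted fit. The full divisor grid is available
  with `t_max_fraction = 1`.
* **Empty rebinned traces** (zero mean counts) make Q undefined; such
  entries are dropped, never imputed. A curve with fewer than four valid
  sampling times is an error.

## Detector corrections

Real photon counters afterpulse (spurious correlated counts, probability
$P_A \sim 1\%$) and have dead time ($t_{\mathrm{dead}} \sim 70$ ns), which
respectively raise and lower the measured Q. `correct_moments()` applies the
first-order moment correction with $\delta = t_{\mathrm{dead}}/T$; it is
valid only while $\langle k\rangle\delta \ll 1$, so the function warns above
$\langle k\rangle\delta = 0.1$ and refuses above $0.5$ (the method statement
gives only the asymptotic condition; the two thresholds are this package's
choice). Background light from a blank measurement enters as a rate and
rescales the curve by the constant $(1 - \langle b\rangle/\langle
k\rangle)^{-1}$ (`background_correct_curve()`); for a stationary trace that
ratio is provably $T$-independent and the code asserts it to $10^{-9}$.
Corrections are applied in the order dead time + afterpulsing (jointly, on
the moments) then background (on the curve).

Because the corrections only *undo* artefacts, the package also ships
injectors (`inject_dead_time()`, `inject_afterpulsing()`,
`inject_background()`) that *create* them on synthetic traces, so the
correction direction and magnitude are testable: dead time is emulated by
drawing uniform arrival times within each bin and applying nonparalyzable
clipping, afterpulsing by duplicating counts with probability $P_A$ in the
same bin (afterpulse delays are ns-scale, far below any bin width used
here), background by adding per-bin Poisson counts. The direction tests run
at 0.5 MCps where $\langle k\rangle\delta = 0.035$, safely inside the
first-order regime; at 1 MCps the *second-order* residual of the published
correction already reaches $\sim 0.04$ in Q.

## The Monte Carlo simulator

`simulate_trace()` generates ground-truth traces: point emitters in a
periodic box spanning $12\times$ the lateral and axial PSF radii perform a
lattice walk — each time slice $\Delta t$, one step of length
$\varepsilon_i = \sqrt{6 D_i \Delta t}$ along one of the six axis
directions, chosen uniformly — with the slice set by the fastest species via
the Einstein–Smoluchowski relation $\Delta t = \varepsilon_{\max}^2/(6
D_{\mathrm{fastest}})$ and $\varepsilon_{\max} \le 20$ nm to stay in the
Wiener-process regime. Emission per slice is Poissonian with intensity
$\mu_0\,\Delta t\,\mathrm{PSF}(\mathbf r)$. The six-direction lattice walk
(rather than Gaussian displacements) is deliberate: the reference recovery
values this package is validated against were produced by that scheme, and
its discretization bias is part of what those values reflect.

Decisions the method description leaves open, fixed here:

* **Boundaries**: periodic wrapping, which preserves the uniform stationary
  density; with a $12\times$ box the PSF at the faces is
  $e^{-72}$, so wrap-around correlations are immeasurably small.
* **Initial placement**: uniform in the box, no burn-in — uniform *is* the
  stationary distribution under periodic boundaries.
* **Brightness calibration**: $\phi_0 = \mu_0 \Delta t$, i.e. the simulator
  parameter is the same detected-rate-at-maximum quantity the model fits.
* **Emission draw**: one Poisson variate per slice with the summed
  per-particle intensity — distributionally identical to per-particle draws
  (sums of independent Poissons), and several-fold faster.
* **Output binning**: slice counts are summed exactly into bins of the
  requested width rounded to an integer multiple of $\Delta t$.
* **Blinking toggle**: optional per-particle two-state switching with rates
  $k_{\mathrm{on}}, k_{\mathrm{off}}$ (per-slice flip probabilities
  $k\,\Delta t$, initial state drawn from the stationary dark fraction).

One physical subtlety the blinking toggle exposes: for a two-state emitter
the Q amplitude carries an extra $(1-F)$ factor from the reduced *mean*
brightness, so fitting the standard model (which omits that factor, treating
$\mu_0$ as the effective brightness) to a blinking trace recovers
$\mu_0^{\mathrm{eff}} \approx \mu_0 (1-F)$ together with the correct $F$ and
$\tau_F$ shape parameters. The fitted $F$ and the short-$T$ rise are the
physically meaningful blinking observables; fitted brightness under blinking
is an effective quantity, as it is for experimental dyes.

### What the simulator does and does not emulate

It reproduces Brownian diffusion statistics, Poisson shot noise, multiple
species, and optional binary blinking. It does **not** include photobleaching,
triplet kinetics, detector artefacts (these are *injected* separately, see
above), flow, or optical saturation. Passing the recovery tests therefore
demonstrates the estimator and fit machinery on ideal-detector data; real
measurements additionally rely on the correction path, which is validated
only against the synthetic artefact injectors.

## Fitting

`fit_msmr()` minimizes the unweighted sum of squared residuals of
$\mu(T)$ with a Levenberg–Marquardt optimizer under box bounds
($\mu_0 \in (0, 10^9)$ cps, $\tau_D \in (10^{-7}, 10)$ s,
$F \in [0, 0.99]$, $\tau_F \in (10^{-8}, 10^{-2})$ s — the upper corners
keep the optimizer off the divergent $F \to 1$ region), with relative
tolerances $10^{-10}$ and at most $10^4$ function evaluations. Unweighted
least squares is the default because the reference analysis states no
weighting; per-point weights are accepted. The aspect ratio $r$ is fixed by
default and should come from a calibration measurement: above $r \approx 3$
the model is nearly flat in $r$ (the $r=5$ and $r=10$ curves practically
coincide), so leaving it free is ill-posed and triggers a warning. Standard
errors come from the residual-variance-scaled inverse of the approximate
Hessian, computed with diagonal pre-scaling because the raw matrix mixes
parameter scales across ten decades. Starting values (`initial_guess()`)
use the plateau of the positive part of the curve for $\mu_0$ and the
log-interpolated half-plateau crossing for $\tau_D$.

Replicates can be combined both ways used in practice: average the curves
point-by-point and fit once (`average_curves()`, the convention for
simulation studies), or fit each and average the parameters
(`aggregate_fits()`, the convention for repeated measurements of one
sample; non-converged fits are excluded and counted).

The fitted diffusion time converts to a diffusion coefficient via
$D = r_0^2/(4\tau_D)$ (`diffusion_coefficient()`), with $r_0$ from a
calibration measurement.

## Validation problem sizes

The end-to-end recovery checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) run the full study protocol: five 10 s simulations
per condition at $r_0 = 0.4\ \mu$m, $r = 1$, 20 particles, $D = 50\ \mu$m²/s
(time slice $1.33\ \mu$s, 7.5 M slices per run), for input brightnesses of
40 and 100 kCps, plus a $D = 100\ \mu$m²/s condition run as five 5 s traces
— a deliberate size reduction that leaves per-point statistics at the
shortest sampling times unchanged (same bin counts per unit time) while
halving the number of independent diffusion transits, which is why the
diffusion-recovery band for that condition is wider. Each condition's five
curves are averaged and fitted with the diffusion-only model, $r$ fixed
at 1. Typical recoveries are $\mu_0 = 39$–$41$ kCps for input 40,
$100$–$103$ for input 100, and $D = 47$–$51$ for input 50.

## Known limitations

* Single diffusing species per fit; no two-component or global fitting.
* Isomerization is the binary on/off model only; multi-fluorophore
  birth–death photophysics (relevant for heavily labelled polymers) is
  outside scope.
* The afterpulsing correction is first order; second-order afterpulsing and
  delay-distribution effects are not modelled.
* The divisor-grid estimator requires the trace length to have many
  divisors to produce a dense curve; lengths near primes give sparse grids
  (the simulator's defaults produce highly composite lengths).
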