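# msmr — mean single molecule rate analysis for fluorescence fluctuation spectroscopy

`msmr` analyses binned photon-count traces from fluorescence fluctuation
spectroscopy (FFS) experiments via the sampling-time dependence of Mandel's
Q parameter. For counts `k` accumulated in bins of width `T`,

    Q(T) = (⟨k²⟩ − ⟨k⟩² − ⟨k⟩) / ⟨k⟩,        μ(T) = Q(T) / T

and the *mean single molecule rate* μ(T) obeys the closed-form model

    μ(T) = γ₂ · μ₀ · Γ_diff(T; τ_D, r) · Γ_iso(T; F, τ_F)

with γ₂ = 1/(2√2) for a 3D Gaussian detection volume. The plateau of μ(T)
at short sampling times gives the single-molecule brightness rate μ₀
(counts/s per molecule at the detection-volume maximum) — independent of
concentration — and its decay gives the diffusion time τ_D, hence
D = r₀²/(4 τ_D). The optional Γ_iso term models on/off dark-state blinking
(dark fraction F, relaxation time τ_F) of cyanine-type dyes. The package is
aimed at single-molecule biophysicists who want brightness and diffusion
estimates from photon traces — e.g. for fluorescent-stain DNA sizing — with
explicit corrections for the detector artefacts (afterpulsing, dead time,
background) that dominate Q at short sampling times.

It provides:

* closed-form model functions with cancellation-safe small-argument series
  (`binning_diffusion()`, `binning_isomerization()`, `msmr_model()`),
* the divisor-grid estimator turning a trace into an empirical curve
  (`msmr_curve()`, `rebin()`, `mandel_q()`),
* first-order afterpulsing/dead-time moment corrections and background
  rescaling (`correct_moments()`, `background_correct_curve()`), plus
  synthetic artefact injectors for validation,
* a lattice-walk Monte Carlo simulator of diffusing (optionally blinking)
  emitters in a 3D Gaussian volume (`simulate_trace()`), compiled with Rcpp,
* Levenberg–Marquardt model fitting with bounds and replicate handling
  (`fit_msmr()`, `average_curves()`, `aggregate_fits()`),
* a YAML-driven pipeline (`run_pipeline()`) and a thin command-line wrapper
  (`inst/cli/msmr.R` with `simulate`, `msmr`, `fit`, `pipeline` subcommands).

## Worked example

Simulate 2 s of 20 molecules (D = 50 µm²/s, μ₀ = 100 kCps) diffusing
through a spherical detection volume of r₀ = 0.4 µm, then estimate and fit:

```r
library(msmr)

cfg <- sim_config(sim_species(D = 50, count = 20, mu0 = 1e5),
                  psf_geometry(r0 = 0.4, z0 = 0.4),
                  duration = 2, seed = 42)
tr <- simulate_trace(cfg)
tr
#> photon trace: 1500000 bins of 1.33333e-06 s (T_obs = 2 s), 4,863 counts, mean rate 2431.5 cps

cur <- msmr_curve(tr)
head(as.data.frame(cur)[, c("T_s", "Q", "mu_cps", "n_bins")], 4)
#>            T_s          Q   mu_cps  n_bins
#> 1 1.333333e-06 0.04528771 33965.79 1500000
#> 2 2.666667e-06 0.09016416 33811.56  750000
#> 3 4.000000e-06 0.14079837 35199.59  500000
#> 4 5.333333e-06 0.18567481 34814.03  375000

fit <- fit_msmr(cur, initial = initial_guess(cur, r = 1), fixed = "r")
fit
#> mSMR fit (converged, 61 points, SSR = 1.964e+07)
#>   mu0   101197 +- 330
#>   tauD  0.000948614 +- 1.79e-05
#>   r     1 (fixed)
#>   F     0 (fixed)
#>   tauF  0.000230116 (fixed)

diffusion_coefficient(fit$params$tauD, r0 = 0.4)
#> [1] 42.2
```

Reading the output: the short-T plateau of `mu_cps` sits near
γ₂·μ₀ ≈ 35.4 kCps, and the fit recovers the input brightness
(101 kCps vs 100 input) from a trace whose *mean* count rate is only
2.4 kCps — brightness per molecule, not intensity, is the observable. A
single 2 s trace leaves several-percent scatter on τ_D (here D = 42 vs 50
input); the validation protocol below averages five 10 s runs, which brings
the diffusion recovery within a few percent.

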