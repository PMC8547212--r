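Package: msmr
Title: Mean Single Molecule Rate Analysis for Fluorescence Fluctuation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the sampling-time-dependent Mandel Q parameter and the mean
    single molecule rate (mSMR) from binned photon-count traces, corrects measured
    photon-count moments for detector afterpulsing and dead time and mSMR amplitudes
    for background noise, and fits closed-form diffusion and on/off isomerization
    models to recover single-molecule brightness rates, diffusion times and
    coefficients, and dark-state fractions. Includes a lattice-walk Monte Carlo
    simulator of Brownian diffusion through a 3D Gaussian detection volume that
    serves as fixture generator and end-to-end validation oracle.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
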