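Package: neqafs
Title: Nonequilibrium Allele Frequency Spectra and Selection-Drift Measures
    After a Change in Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and Monte-Carlo machinery for the Poisson random field
    model of allele-frequency evolution in a population whose size changes
    instantaneously from N to kappa*N at a time t*.  Provides the equilibrium
    site-frequency intensity, fixation probabilities and rates under the
    Wright-Fisher diffusion with genic selection, a negative Gamma
    distribution of fitness effects, the nonstationary allele frequency
    spectrum after one or several step changes in population size, and the
    resulting time-dependent measures of selection efficacy (piN/piS and the
    cumulative fixation-rate ratio) and of genetic drift (diversity-based and
    harmonic-mean effective population sizes).  Expectations over allele
    frequency paths are supplied either by a deterministic Crank-Nicolson
    solver of the backward Kolmogorov equation or by discrete Wright-Fisher
    simulation, behind a common engine interface.  Includes kappa-sweep
    tables and log-log slope fits of the selection-drift relationship.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    pracma,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
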