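Package: lvcdyn
Title: Linear Vibronic Coupling Models from Overlap-Based Diabatization,
    with Quantum Wavepacket Dynamics and Vibronic Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct linear vibronic coupling (LVC) Hamiltonians for
    multichromophoric systems from adiabatic excited-state data by Loewdin
    orthogonalization of reference/adiabatic overlap matrices, extract linear
    coupling constants by central finite differences along dimensionless
    normal-mode displacements, and simulate the resulting diabatic models:
    closed-form diabatic minima and reorganization energies, numerically exact
    nonadiabatic wavepacket propagation on truncated harmonic-oscillator
    product bases with diabatic populations and potential-energy expectations,
    and vibronic absorption spectra from autocorrelation functions with
    Gaussian broadening. A seeded synthetic electronic-structure backend
    emulates the excited-state layer so the full pipeline is testable without
    a quantum-chemistry code. Results are returned as tibbles with tidy(),
    glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
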