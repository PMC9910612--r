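Package: destfit
Title: Two-Pool Exchange Modeling of Dark-State Saturation Transfer and
    Relaxation NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring spectroscopically dark, exchanging species
    from solution NMR data. Implements a two-pool Bloch-McConnell simulator
    for continuous-wave saturation (CEST/DEST Z-spectra) and observed
    relaxation rates under chemical exchange; a Boltzmann/Arrhenius
    thermodynamic-kinetic parameterization of the monomer-assembly
    equilibrium; joint fitting of temperature series of R2 and Z-spectrum
    dip widths with parameter-recovery reporting; Stejskal-Tanner
    pulsed-field-gradient diffusion fitting and gradient-schedule design;
    and Bloembergen-Purcell-Pound relaxation curves with
    Stokes-Einstein(-Debye) size, mobility and hydration conversions.
    Includes a synthetic-study generator so the whole pipeline is testable
    end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
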