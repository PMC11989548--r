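Package: statinfde
Title: Fractional-Order Dynamics of Statin Action on Lipid Peroxidation
    and Arterial Mineralization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates the effect of statin dose on LDL-driven lipid
    peroxidation and atheromatic plaque mineralization with
    fractional-order (Caputo) differential equations.  Provides a
    predictor-corrector (PECE) fractional Adams-Bashforth-Moulton solver
    validated against Mittag-Leffler closed forms, an FTIR band registry
    that converts vibrational wavenumbers to molar bond energies, coupled
    HDL/oxidative-stress/LDL dynamics with a malondialdehyde observable,
    an arterial wall deformation (plaque growth) model, and a sweep over
    the fractional order - read as a statin concentration indicator -
    that locates the non-monotonic toxic reversal point of the dose
    response.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
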