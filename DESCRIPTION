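Package: saptfit
Title: Component-Resolved Intermolecular Force Fields from SAPT Energy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Physics-motivated models for the four symmetry-adapted
    perturbation theory (SAPT) interaction-energy components of small
    organic dimers: density-overlap exchange, damped multipole
    electrostatics, Thole-style iterated induction, and Tang-Toennies
    damped dispersion. Atom-typed global parameters are fitted to
    reference component energies by quasi-Newton minimization of a
    composite loss, with greedy training-set augmentation, error
    reporting, and center-of-mass potential-energy scans. A synthetic
    benchmark generator supplies idealized monomers covering eight
    organic functional-group classes, plausible atomic properties, and
    model-consistent reference energies for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
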