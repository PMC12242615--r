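Package: nrtlsac
Title: NRTL-SAC Solubility Modeling and Melting-Property Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-predictive solubility modeling for pharmaceutical compounds
    with the Non-Random Two-Liquid Segment Activity Coefficient (NRTL-SAC)
    model. Computes residual and Flory-Huggins combinatorial activity
    coefficients for mixtures of molecules described by four conceptual
    segment numbers (hydrophilic X, polar-attractive Y-, polar-repulsive Y+,
    hydrophobic Z), solves the simplified solid-liquid-equilibrium relation
    for saturation mole fractions, and estimates a solute's segment numbers,
    enthalpy of fusion and melting temperature from small solubility datasets
    by bounded multistart Nelder-Mead optimization. Includes a synthetic-data
    generator emulating a four-solvent, three-temperature study design,
    tidy accessors for bundled parameter tables, and ggplot2 visualizations
    of solubility curves and multistart objective landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
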