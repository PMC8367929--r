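Package: mtxpbpk
Title: Minimal Physiologically Based Pharmacokinetics of High-Dose
    Methotrexate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and population identification toolkit for a minimal
    physiologically based pharmacokinetic (PBPK) model of intravenous
    high-dose methotrexate in adults.  Patient covariates (sex, age, weight,
    height, hematocrit, serum creatinine) individualize compartment volumes,
    plasma flows, and renal function (CKD-EPI eGFR with a full-age-spectrum
    reference cap); a five-compartment stiff ODE system describes plasma,
    interstitial and intracellular drug disposition with saturable tubular
    secretion/reabsorption and carrier-mediated cellular exchange.  Includes
    a mean-squared-log-error objective, grid-search plus simplex population
    fitting, patient-resampling bootstrap, virtual-population generators,
    tidy accessors, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
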