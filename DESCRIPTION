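Package: remipkpd
Title: Population Pharmacokinetic-Pharmacodynamic Modelling and
    Target-Controlled Infusion Simulation for Remimazolam and its
    Metabolite CNS7054
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a population pharmacokinetic and
    pharmacodynamic model of the intravenous benzodiazepine remimazolam and
    its pharmacologically inactive metabolite CNS7054: a three-compartment
    mammillary model with arteriovenous delay and a sequential metabolite
    depot model, a proportional-odds model for the Modified Observer's
    Assessment of Alertness/Sedation (MOAA/S) score and a sigmoidal Emax
    model for the bispectral index (BIS), both with a competitive-antagonist
    tolerance term driven by the metabolite. Provides covariate-based
    parameter individualisation (age, weight, sex, opioid co-administration,
    hepatic and renal dysfunction, ECMO and ICU adjustments), exact
    matrix-exponential simulation under bolus/infusion schedules,
    plasma- and effect-site-targeted TCI planning with sedation and
    anaesthesia dosing scenarios, virtual-cohort generation with log-normal
    interindividual variability, and desk-scale parameter recovery (MAP
    empirical-Bayes etas and pooled maximum likelihood) with MdPE/MdAPE
    predictive-performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    patchwork,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
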