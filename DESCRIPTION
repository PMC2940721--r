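Package: thermocrm
Title: Thermodynamics-Based Models of Enhancer Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-thermodynamic modeling of transcriptional regulation by
    cis-regulatory modules (CRMs, enhancers). Given CRM sequences, transcription
    factor binding motifs (PWMs) and TF concentration profiles, predicts the
    expression readout of each CRM as the equilibrium occupancy of the basal
    transcriptional machinery, summing over all binding-site configurations with
    exact dynamic-programming partition functions. Supports direct-interaction
    and short-range ("quenching") repression, additive, multiplicative and
    limited-contact activator action, and cooperative DNA binding. Includes
    parameter training (Nelder-Mead and quasi-Newton with restarts, correlation
    and sum-of-squared-error objectives), k-fold cross-validation, permuted-PWM
    negative controls, knock-down analysis, model comparison, evolutionary
    conservation filters for binding sites, and a synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
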