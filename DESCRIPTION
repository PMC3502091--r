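Package: macawake
Title: Compartmental Simulation of Inhaled Anesthetic Washout, Emergence, and
    Rehypnotization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A physiologically based, perfusion-limited compartment model of
    inhaled anesthetic uptake and distribution (breathing circuit, alveoli,
    and vessel-rich, muscle, and fat tissue groups), with protocol machinery
    for overpressure induction, alveolar partial-pressure clamping, high-flow
    washout under normo- or hyperventilation, and post-recovery
    hypoventilation. Computes emergence metrics: ventilatory clearance,
    time to MACawake (0.3 MAC in the vessel-rich group), peak rebound
    partial pressures, and rehypnotization verdicts for desflurane,
    sevoflurane, and isoflurane, together with scenario grids and
    body-habitus perturbations for sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
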