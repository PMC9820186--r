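Package: ictalsim
Title: Neural-Mass Simulation and Analysis of Ictal and Interictal Discharges
    under Low-Frequency Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-population neural-mass model of the 4-aminopyridine
    epilepsy model in entorhinal cortex, with dynamic extracellular potassium,
    intracellular sodium and chloride concentrations and Na-K pump mediated
    seizure termination, under periodic low-frequency stimulation protocols.
    Provides the accompanying measurement pipeline: detection and classification
    of ictal versus interictal discharges, spike-train firing-pattern and
    action-potential waveform metrics, potassium-selective microelectrode
    calibration and transient statistics, and Boltzmann dose-response fitting of
    discharge-induction probability. A synthetic-data generator renders voltage,
    current and electrode traces with known ground truth so every analysis stage
    is testable by round-trip recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
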