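Package: thermorun
Title: Two-Compartment Thermoregulation Modeling of Treadmill Exercise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing core body temperature dynamics of small
    animals during incremental treadmill exercise with a two-compartment
    (core and skeletal muscle) heat-balance model. Converts open-circuit
    indirect calorimetry (VO2, VCO2) and treadmill workload into heat
    production, solves the linear two-compartment temperature system in
    closed form per measurement interval, estimates core heat production
    and the core-to-environment heat dissipation coefficient by
    Metropolis-Hastings sampling of a Gaussian likelihood over group-mean
    telemetry series, reconstructs unobserved muscle temperature with
    posterior uncertainty, and compares treatment groups with z-tests.
    Includes a synthetic cohort generator (protocol-driven oxygen uptake,
    per-animal variability, exhaustion thresholds and group truncation)
    so the whole pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
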