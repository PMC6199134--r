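Package: autoresus
Title: Simulation and Analysis of Neonatal Autoresuscitation Assays
Version: 0.1.0
Authors@R: person("Plethysmography", "Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing repeated asphyxia-induced apnea
    (autoresuscitation) assays in neonatal rodents: detection of breaths,
    heart beats and gasps in head-out plethysmograph and ECG-style traces;
    baseline cardiorespiratory measures (breathing frequency, tidal volume,
    minute ventilation, oxygen consumption, ventilatory equivalents);
    interval-variability descriptors (SD, RMSSD, Poincare axes); per-bout
    recovery latencies to 63% of pre-bout baseline; gasp-train profiling;
    and cohort-level inference (Lancaster mid-P Fisher exact test, odds
    ratios, logistic mortality models, breathing/heart-rate coupling
    regression with a runs test). A synthetic trace generator with full
    ground-truth annotation stands in for raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
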