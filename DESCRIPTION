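Package: larvascreen
Title: Two-Stage Zebrafish Locomotion and Electrophysiology Screen for
    Antiseizure Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for phenotype-based
    antiepileptic drug screens in scn1Lab mutant zebrafish larvae. Provides a
    seeded synthetic-data generator for larval swim trajectories, local field
    potential (LFP) traces and 96-well plate layouts; locomotion metrics and
    three-stage seizure scoring; control-variability-derived hit thresholds
    with toxicity and hyperexcitability calls; epileptiform event detection by
    amplitude and duration gating; and a two-stage screening funnel
    (behavioral hit calling confirmed by electrographic suppression) with
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
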