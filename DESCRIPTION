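Package: cyclofit
Title: Host-Guest Binding, Photophysics and Liposomal Formulation
    Analysis for Cyclodextrin Drug-Delivery Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for drug-cyclodextrin-liposome
    formulation studies. Fits 1:1 and 1:2 host-guest binding isotherms to
    fluorescence anisotropy titrations with stoichiometry selection,
    extracts complexation enthalpy and entropy by linear van't Hoff
    analysis, classifies Higuchi-Connors phase-solubility diagrams and
    computes stability constants, analyses time-correlated single photon
    counting decays and Stern-Volmer quenching with linear-region
    masking, quantifies liposomal encapsulation efficiency and
    first-order release kinetics, and estimates IC50 values from MTT
    dose-response plates with replicate-level comparison. Includes seeded
    synthetic-data generators for every input format and a pipeline
    runner with plain-text and machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
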