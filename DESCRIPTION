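Package: adaptscan
Title: CRISPR Spacer-Acquisition Amplicon Analysis and Adaptation Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-throughput CRISPR spacer-acquisition
    experiments in type I-F systems: repeat-anchored extraction of expanded
    arrays from barcoded leader-anchored amplicons, exact protospacer mapping
    on circular replicons, PAM slip/flip classification, acquisition-order
    statistics (strand fractions, signed travel distances, weighted heatmaps),
    sliding-window density tracks, hotspot detection and summary tables.
    Includes a generative simulator of naive, primed and interference-driven
    ("targeted") adaptation that emits amplicon reads together with a
    ground-truth event log, so every analysis stage can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
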