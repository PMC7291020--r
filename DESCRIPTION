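Package: lipidflow
Title: Untargeted Lipidomics Feature-Table Processing and Biomarker Discovery
Version: 0.1.0
Authors@R: person("LipidFlow", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-acquisition workflow for untargeted LC-MS lipidomics:
    blank filtering, QC-based coefficient-of-variation filtering, LOESS
    signal-drift correction, protein or total-ion-count normalization,
    isomer summation, lipid-class aggregation, generalized-log transform
    and autoscaling, univariate (volcano) and multivariate (PLS-DA with
    VIP scores and leave-one-out validation) statistics, a combined
    fold-change/p-value/VIP biomarker index (the impact factor), ranked
    lipid-ontology-style enrichment, acyl-chain composition profiling,
    and a synthetic batch simulator with ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
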