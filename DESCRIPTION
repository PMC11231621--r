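Package: rnteract
Title: Logical Data Model and Temporal Mining of Nurse-EHR Audit Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structures electronic health record (EHR) audit logs into a
    nurse-centric logical data model: temporal task vectors (NTask) on a
    configurable time grid plus static vectors of nurse characteristics
    (NType), patient-panel features (NPanel) and long-term outcomes
    (NOutcome), each governed by reconfigurable value sets. Trajectories are
    clustered into archetypical activity patterns with deterministic
    k-medoids on Hamming distances; per-cluster enrichment and depletion of
    static properties is quantified with Fisher exact and seeded permutation
    tests under Benjamini-Hochberg false discovery rate control, and a
    cluster-conditional rate table serves as a baseline outcome predictor.
    A seeded simulator generates synthetic audit-event streams with planted
    archetypes (block versus continuous charting) so the full pipeline can
    be exercised and validated without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vctrs,
    withr,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
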