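Package: dmnmod
Title: Race-Moderated Default Mode Network Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing whether a grouping variable (race) moderates the
    relationship between default-mode-network (DMN) node-pair functional
    connectivity and Alzheimer's disease biomarkers (composite cognition,
    CSF beta-amyloid 1-42, CSF total tau). Implements the DMN subsystem node
    model (dorsomedial, medial temporal, midline core), per-subject
    connectivity from component time courses (volume discarding, 0.01-0.08 Hz
    band-pass, pairwise Pearson correlation), framewise-displacement quality
    control, per-node-pair moderation regressions with covariate adjustment
    and an amyloid-positivity gate, Benjamini-Hochberg and Storey q
    multiple-testing control, subsystem-mean ANCOVA, and a bootstrap
    enrichment test for concentration of moderation effects in a subsystem
    block. A synthetic cohort generator produces subject records, component
    time courses, and motion traces with plantable moderation effects so the
    full pipeline is testable without access to protected human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
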