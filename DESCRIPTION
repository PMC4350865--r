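Package: drugkb
Title: Integrated Drug Knowledge Bases for Medication Risk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous drug-knowledge sources (a pharmaceutical
    interaction/side-effect source, a molecular drug source, a MedDRA-style
    side-effect source, and a pathway/disease source) into one provenance-tagged
    knowledge base. Supports drug-drug, drug-molecule and drug-pathway interaction
    queries, single and cumulative side-effect detection, drug-induced disease
    screening of a medication profile, cytochrome P450 dosage flags,
    inter-source concordance statistics, and export of level-coded radial
    network documents for visualization. Includes a deterministic synthetic
    source generator with planted ground truth for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
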