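Package: bctmsg
Title: Generative Content Development and Quality Control for Brief-Message Health Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds banks of brief (SMS) health-intervention messages from a
    structured behavior change technique (BCT) database. Renders attributed
    system/user prompts by token substitution, drives a pluggable
    chat-completion backend (with a deterministic offline mock), and
    post-processes responses into tagged message banks. Quality-checks every
    message against SMS deliverability standards (GSM 03.38 septet encoding,
    160-character limit) and readability (Flesch-Kincaid grade with a
    configurable ignore-word adjustment), and quantifies message diversity via
    embedding projections (PCA, t-SNE) and a cross-dataset BCT relevance
    comparison based on centered embeddings and top-k alignment accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    Rtsne,
    stats,
    stringi,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
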