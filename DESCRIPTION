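Package: vustriage
Title: Triage of Missense Variants of Uncertain Significance in Ion-Channel Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles classified missense-variant catalogs for a protein
    family from ClinVar-, Humsavar-, Ensembl- and gnomAD-style exports,
    benchmarks pathogenicity predictors (sensitivity, specificity, Matthews
    correlation, accuracy, ROC/AUC and optimal thresholds), transfers
    likely-pathogenic annotations across paralogues through a multiple
    sequence alignment gated by a Zvelebil-style physicochemical
    conservation score, detects and classifies sidechain heavy-atom
    contacts between candidate positions in a homotetrameric channel
    structure, and combines the three lines of evidence into tiered
    candidate-pathogenic calls. A seeded synthetic-data generator emulates
    every input so the whole pipeline runs and is tested without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
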