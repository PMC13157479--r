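Package: ophpo
Title: Phenotype Annotation of Ophthalmology Records with the Human Phenotype Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A locally deployable pipeline that converts free-text
    ophthalmology letters into Human Phenotype Ontology (HPO) codes.
    Records pass through translation, segmentation into discrete
    findings, exclusion of normal and negated findings, and mapping of
    each pathological finding to exactly one HPO code by an exact-match
    tier followed by K = 1 nearest-neighbour search in embedding space
    over a layered synonym catalog (standard ontology layer plus a
    locally curated layer with an ignore sentinel). Includes the
    expert-in-the-loop catalog-augmentation workflow, set-based
    evaluation metrics (Jaccard, precision, recall, F1; per-record
    medians and micro-pooled), a synthetic bilingual corpus generator
    with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
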