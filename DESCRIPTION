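Package: camur
Title: Multiple Rule-Based Classification Models for Case-Control Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Induces rule-based classification models (disjunctions of
    threshold conjunctions on gene expression values) from case-control
    RNA-seq FPKM matrices using a RIPPER-style learner, and extracts many
    alternative, near-equivalent models by iteratively eliminating the
    features found in accepted models and re-learning.  Accepted models
    are accumulated in a queryable knowledge base supporting feature
    occurrence counts, conjunction and rule listings, literal threshold
    statistics and feature co-occurrence pairs.  Includes a synthetic
    FPKM-like data generator with planted discriminative genes, CSV
    input/output in the samples-by-genes layout, a command line
    interface and static report rendering.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
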