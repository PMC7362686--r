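Package: netcongruency
Title: Multi-Informant Congruency Analysis of Classroom Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing classroom social networks reported by
    different informants (child peer nominations, teacher ratings, and
    researcher observations). Provides labeled adjacency-matrix input and
    output over a shared roster, the binary-transformation schemes used
    for rating and count networks (Likert cutoffs; chance-level,
    twice-chance and fixed ratio thresholds; half-median and percentile
    frequency thresholds), graph correlation with Quadratic Assignment
    Procedure (QAP) permutation inference, Jaccard overlap of binary
    networks, bootstrap validation of per-child network totals against
    outcome scores, and a synthetic classroom generator with a latent
    play-group structure for testing every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
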