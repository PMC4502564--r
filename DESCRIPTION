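Package: dupliclass
Title: Classification of Evolutionary Processes Retaining Duplicate Genes
    from Multi-Tissue Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies pairs of duplicate genes as conserved,
    neofunctionalized (parent or child copy), subfunctionalized, or
    specialized by comparing Euclidean distances between relative
    multi-tissue expression profiles of the parent copy, the child copy,
    and their single-copy ortholog in a sister species against a
    per-species-pair divergence cutoff (median plus semi-interquartile
    range of single-copy ortholog divergence). Includes quantile
    normalization of expression matrices, parsimony dating of duplication
    events on a rooted species tree, parent/child designation from
    outgroup-alignment evidence, downstream statistics (regression of
    functional conservation on synonymous divergence, tissue-specificity
    comparisons, highest-expressed-tissue enrichment with exact tests and
    Bonferroni correction), and a fully seeded synthetic-data generator
    that plants ground-truth retention classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
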