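Package: rpvec
Title: Rank Product Differential Expression and Fold-Change Vector
    Analysis for 2x2 Factorial RNA-Seq Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a reproducible analysis pipeline for bulk RNA-seq
    experiments with a 2x2 factorial exposure design (for example pre-natal
    and post-natal glucocorticoid treatment, giving groups CC, BC, CB and
    BB): upper-quartile normalization of raw counts, a variance-stabilising
    log2(x + 32) transform, principal-component sample QC, non-parametric
    RankProducts differential expression with permutation-based
    percentage-of-false-positives over all six pairwise group contrasts,
    vector analysis of paired between-replicate fold changes with
    permutation significance and sector classification, and combination
    of the two vector analyses into four factorial response categories
    (common, cumulative, pre-natal-specific and post-natal-specific).
    A seeded negative-binomial simulator generates count matrices with the
    factorial structure and planted effects so that every stage of the
    pipeline can be exercised and calibrated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
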