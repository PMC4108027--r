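Package: copymin
Title: Minimum Ancestral Gene Copy-Number Inference from Gene Family Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of bootstrap-annotated gene family trees and
    parsimony-style inference of the minimum number of gene-family members in
    the common ancestor of two lineages, as used in comparative studies of
    land-plant gene families (e.g. pectin-related families in the moss
    Physcomitrella patens versus vascular plants). Provides Newick input and
    output with bootstrap supports stored as internal node labels, collapsing
    of poorly supported nodes into polytomies, outgroup rooting that preserves
    supports, lineage-aware clade spanning tests, a per-family per-species
    gene census, and a duplication-loss gene-tree simulator along a reference
    species tree for validating the inference against known copy numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
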