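Package: mulrec
Title: Allopolyploidy Inference by Gene-Tree Reconciliation with Multi-Labelled Species Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers ancient allopolyploidy from collections of rooted gene trees by
    reconciling them against multi-labelled (MUL) species trees. Enumerates the full
    candidate space of MUL trees obtained by placing a polyploid clade (H1) and a second
    parental lineage (H2) on a species tree, performs LCA duplication-loss reconciliation
    with an exhaustive search over polyploid-group subgenome assignments, applies
    polyploid-group and gene-copy-number filters to gene trees, classifies gene families
    into homeolog retention/loss scenarios (T1/T2/T3), and tests per-scenario functional
    category enrichment with exact hypergeometric p-values and Benjamini-Hochberg
    adjustment. Includes a seeded simulator of allopolyploid gene families with
    subgenome-biased loss, small-scale duplication, and topological noise for validation
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
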