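#!/usr/bin/env Rscript
# Stage 3: enumerate the candidate reference space.
#
# One singly-labelled candidate plus every MUL tree obtained by placing a
# polyploid clade H1 and a second-subgenome attachment H2 on the 8-taxon
# species tree: 181 candidates in all, matching the size of the search space
# the method explores on this sampling.

suppressMessages(library(mulrec))

stree <- read_species_tree("results/sim/species_tree.nwk")
cands <- enumerate_candidates(stree)
tab <- candidates_table(cands)

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d candidates (%d singly-labelled + %d MUL placements)",
                nrow(tab), sum(tab$kind == "singly_labelled"),
                sum(tab$kind == "mul")))
message("wrote results/candidates.tsv")
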