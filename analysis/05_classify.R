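#!/usr/bin/env Rscript
# Stage 5: homeolog retention/loss scenario classification.
#
# Each deep-filtered gene tree, restricted to the focal clade, is matched
# against the three scenario patterns: T1 (one copy lost in cladeB), T2 (one
# copy lost in cladeA), T3 (both copies retained), else U. The loss-dominance
# fraction (trees with more losses than duplications against the best
# candidate) summarises how loss-driven the families are.

suppressMessages(library(mulrec))

deep <- read_gene_trees("results/filter/deep.nwk")
deep_idx <- as.integer(readLines("results/filter/deep_index.txt"))
map <- read_species_map("results/sim/species_map.tsv")

cls <- classify_trees(deep, map, mode = "strict")
cls$tree_index <- deep_idx[cls$tree_index]
tl <- tally_scenarios(cls$label)

dir.create("results/classify", showWarnings = FALSE, recursive = TRUE)
write.table(cls, "results/classify/labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tl, "results/classify/tally.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

best <- read.delim("results/scores/best_detail.tsv")
lvr <- loss_vs_retention(best)
write.table(data.frame(fraction_losses_gt_dups = lvr),
            "results/classify/loss_vs_retention.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(paste(sprintf("%s=%d (%.1f%%)", tl$label, tl$n, 100 * tl$fraction),
              collapse = "  "))
message(sprintf("families with losses > duplications vs best candidate: %.1f%%",
                100 * lvr))
# sanity: compare against the generating truth
truth <- read.delim("results/sim/truth.tsv")
agree <- mean(cls$label == truth$label[cls$tree_index])
message(sprintf("agreement with simulator truth labels: %.1f%%", 100 * agree))
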