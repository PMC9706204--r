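#!/usr/bin/env Rscript
# Stage 2: gene-tree filtering.
#
# The preliminary filter caps the polyploid-group count at 8 per tree (keeps
# the subgenome assignment search bounded); the deep filter then restricts
# copy number to 1-4 per species with every species present. Both datasets
# (preliminary and deep) are carried forward and scored separately.

suppressMessages(library(mulrec))

trees <- read_gene_trees("results/sim/gene_trees.nwk")
map <- read_species_map("results/sim/species_map.tsv")

prelim <- preliminary_filter(trees, focal_species(map))
deep <- deep_filter(prelim$kept, c(outgroup_species(map), focal_species(map)))

dir.create("results/filter", showWarnings = FALSE, recursive = TRUE)
write_gene_trees(prelim$kept, "results/filter/preliminary.nwk")
write_gene_trees(deep$kept, "results/filter/deep.nwk")
writeLines(as.character(prelim$kept_index), "results/filter/preliminary_index.txt")
writeLines(as.character(prelim$kept_index[deep$kept_index]),
           "results/filter/deep_index.txt")
rej <- rbind(prelim$rejected, deep$rejected)
write.table(rej, "results/filter/rejections.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("preliminary: kept %d / %d", length(prelim$kept), length(trees)))
message(sprintf("deep:        kept %d / %d", length(deep$kept), length(prelim$kept)))
if (nrow(rej)) {
  message("rejections by reason:")
  print(table(rej$reason))
} else {
  message("no rejections under the study conditions")
}
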