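#!/usr/bin/env Rscript
# Stage 1: generate the study dataset.
#
# 500 gene families descend from an allopolyploid origin of the focal clade
# (subgenome join at the focal-clade ancestor), with subgenome-biased
# clade-level loss (a = 0.4 against the "+" copy in cladeB, d = 0.35 against
# the "*" copy in cladeA) and 5% per-leaf loss noise - the package's standard
# study conditions. Everything downstream reads the files written here.

suppressMessages(library(mulrec))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- sim_config(n_families = 500L, seed = seed)
sim <- simulate_dataset(cfg)
write_simulation(sim, "results/sim")
writeLines(write_newick(cfg$species_tree), "results/sim/species_tree.nwk")

tl <- tally_scenarios(sim$truth$label)
message(sprintf("simulated %d families (seed %d, %d resampled)",
                length(sim$trees), seed, sim$n_resampled))
message(sprintf("true placement: %s", cfg$candidate$id))
message(paste(sprintf("%s=%d (%.1f%%)", tl$label, tl$n, 100 * tl$fraction),
              collapse = "  "))
message("wrote results/sim/")
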