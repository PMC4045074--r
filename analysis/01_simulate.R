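#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 15-month drinking-water survey that every
# later stage analyzes, and write its on-disk artifacts under results/data/.
# Scale: 1,200 OTUs (the survey had 4,369; scaled for desk runtime), 10
# locations (DWTP + 3 sectors x 3), 881 pipe sections, ~46 km of mains.

suppressMessages(library(aquadyn))
seed <- 20140527L  # fixed master seed for the whole workflow
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

g <- generate(synthetic_spec(n_otus = 1200, seed = seed))

write_otu_table(g$table, "results/data/otu_table.tsv", format = "wide")
write_sample_metadata(g$meta, "results/data/metadata.csv")
ape::write.tree(g$tree, "results/data/otus.nwk")
write_pipe_inventory(g$pipes, "results/data/pipes.csv")
saveRDS(g$truth, "results/data/truth.rds")  # local scratch; not a deliverable

message(sprintf("table: %d samples x %d detected OTUs, %s reads",
                nrow(g$table$counts), ncol(g$table$counts),
                format(sum(g$table$counts), big.mark = ",")))
message(sprintf("pipes: %d sections, %.1f km, %.0f m^2 surface",
                nrow(g$pipes), sum(g$pipes$length_m) / 1000,
                sum(pi * g$pipes$diameter_m * g$pipes$length_m)))
message(sprintf("planted: clusters of %d + %d OTUs, occupancy law %s (alpha = %g)",
                length(g$truth$cluster_members$cluster1),
                length(g$truth$cluster_members$cluster2),
                g$truth$occupancy_model, g$truth$occupancy_alpha))
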