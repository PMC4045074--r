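#!/usr/bin/env Rscript
# Stage 5: interspecific occupancy-abundance modeling — maximum-likelihood
# comparison of the five model forms on (mu, f) points extracted from the
# rarefied table, plus the month-randomization envelope for the monthly
# Hanski-Gyllenberg alpha. Writes results/ioam/.

suppressMessages(library(aquadyn))
dir.create("results/ioam", showWarnings = FALSE, recursive = TRUE)

tab <- read_otu_table("results/data/otu_table.tsv")
meta <- read_sample_metadata("results/data/metadata.csv")
truth <- readRDS("results/data/truth.rds")

events <- rarefy(tab, rarefaction_plan(depth = 834, n_events = 30,
                                       base_seed = 404))
pts <- occupancy_points(events, meta)
message(sprintf("%d occupancy points (max 15 per OTU)", nrow(pts)))

cmp <- compare_models(pts)
write.csv(cmp, "results/ioam/model_comparison.csv", row.names = FALSE)
print(cmp)
message(sprintf("best fit: %s, alpha = %.0f (planted %s, alpha = %g)",
                cmp$model[1], cmp$alpha[1], truth$occupancy_model,
                truth$occupancy_alpha))

# monthly alpha against the within-location month-randomization envelope
# (survey: 1,000 reps; 300 here for runtime)
env <- monthly_alpha_envelope(events, meta, n_reps = 300, seed = 505)
write.csv(env, "results/ioam/monthly_alpha.csv", row.names = FALSE)
inside <- env$alpha_obs >= env$perm_min & env$alpha_obs <= env$perm_max
message(sprintf("monthly alpha inside the permutation envelope: %d of %d months",
                sum(inside), nrow(env)))
# the planted seasonality restructures (mu, f) month by month, so observed
# monthly alpha may sit outside the randomization envelope here; in a
# structureless world it stays inside (see the package's acceptance tests)
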