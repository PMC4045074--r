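#!/usr/bin/env Rscript
# Stage 2: rarefied alpha/beta diversity and the spatial-vs-temporal
# permutation statistics. Writes results/diversity/.

suppressMessages(library(aquadyn))
dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)

tab <- read_otu_table("results/data/otu_table.tsv")
meta <- read_sample_metadata("results/data/metadata.csv")
tree <- read_phylogeny("results/data/otus.nwk")

# the survey rarefies to its shallowest retained sample (834 reads) and
# averages beta diversity over subsampling events (here 20; survey: 1,000)
events <- rarefy(tab, rarefaction_plan(depth = 834, n_events = 20,
                                       base_seed = 101))
message("dropped below depth 834: ",
        paste(attr(events, "report")$dropped_samples, collapse = ", "))

alpha <- alpha_metrics(events[[1]])
write.csv(alpha, "results/diversity/alpha.csv", row.names = FALSE)
md <- meta[match(alpha$sample_id, meta$sample_id), ]
by_season <- tapply(alpha$richness, md$season, mean)
message("mean richness by season: ",
        paste(names(by_season), round(by_season), collapse = ", "))

for (m in c("bray_curtis", "jaccard", "unweighted_unifrac", "weighted_unifrac")) {
  dm <- average_beta(events, metric = m, tree = tree)
  write_distance_matrix(dm, sprintf("results/diversity/%s.dist", m))
}

bc <- read_distance_matrix("results/diversity/bray_curtis.dist")
md <- meta[match(rownames(bc), meta$sample_id), ]
rows <- list()
for (gv in c("calendar_month", "season", "location_id", "sector_id")) {
  pm <- permanova(bc, md[[gv]], n_perm = 999, seed = 7, grouping = gv)
  an <- anosim(bc, md[[gv]], n_perm = 999, seed = 8, grouping = gv)
  bd <- beta_dispersion(bc, md[[gv]])
  rows[[gv]] <- data.frame(grouping = gv, permanova_R2 = pm$statistic$R2,
                           permanova_p = pm$p_value, anosim_R = an$statistic$R,
                           anosim_p = an$p_value, dispersion_F = bd$anova_f,
                           dispersion_p = bd$anova_p)
  message(sprintf("%-14s R2 = %.3f (p = %.3f), ANOSIM R = %.3f", gv,
                  pm$statistic$R2, pm$p_value, an$statistic$R))
}
write.csv(do.call(rbind, rows), "results/diversity/grouping_tests.csv",
          row.names = FALSE)
message("temporal groupings should dominate spatial ones (compare R2 above)")

ord <- pcoa(bc)
write.csv(data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates[, 1:3]),
          "results/diversity/pcoa.csv", row.names = FALSE)
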