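#!/usr/bin/env Rscript
# Apply the species filters (dataset-wide singletons/doubletons, then
# species missing more than 4 of the 7 traits), compute inventory
# completeness, community-weighted means, the Gower dissimilarity between
# species and the 4-axis PCoA trait space.
#
# Reads results/ tables from 01_simulate.R.
# Writes: results/filter_report.csv, results/completeness.csv,
#         results/cwm.csv, results/gower.csv, results/pcoa_scores.csv

library(traitvolume)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
cfg <- analysis_config(rng_seed = seed)

inp <- read_inputs("results/pool_traits.csv", "results/specimens.csv",
                   "results/community_long.csv", "results/sample_meta.csv")

filt <- filter_rare_and_incomplete(inp$community, inp$traits, cfg)
write.csv(as.data.frame(filt$report), "results/filter_report.csv",
          row.names = FALSE)
cat(sprintf("filters: %d rare + %d trait-incomplete species removed; %d species / %d individuals retained\n",
            filt$report$n_rare_removed, filt$report$n_incomplete_removed,
            filt$report$n_species_retained,
            filt$report$individuals_retained))

comp <- do.call(rbind, lapply(split(seq_len(nrow(filt$community$abund)),
                                    filt$community$meta$assemblage),
  function(rows) {
    x <- completeness(colSums(filt$community$abund[rows, , drop = FALSE]),
                      cfg$rare_cutoff)
    data.frame(s_obs = x$s_obs, s_est = x$s_est,
               completeness = x$completeness, estimator = x$estimator)
  }))
comp$assemblage <- rownames(comp)
write.csv(comp, "results/completeness.csv", row.names = FALSE)
cat("inventory completeness (%):",
    sprintf("%s %.1f", comp$assemblage, comp$completeness), "\n")

cwm_tab <- cwm(filt$community, filt$traits)
write.csv(cwm_tab, "results/cwm.csv", row.names = FALSE)

std <- standardize_traits(filt$traits)
g <- gower_dissim(std)
write.csv(g, "results/gower.csv")
space <- trait_pcoa(g, cfg$n_axes)
cat(sprintf("PCoA: %d axes represent %.1f%% of trait variation\n",
            cfg$n_axes, 100 * space$variance_fraction))
write.csv(data.frame(species_id = rownames(space$scores), space$scores),
          "results/pcoa_scores.csv", row.names = FALSE)
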