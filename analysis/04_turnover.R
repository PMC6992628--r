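#!/usr/bin/env Rscript
# Taxonomic (Bray-Curtis) and functional (TPD-overlap) turnover between
# samples: PERMANOVA (assemblage * area, sequential SS, 999 permutations),
# PERMDISP on assemblage groups, and NMDS ordinations.
#
# Reads results/ tables from 01. Writes results/permanova_*.csv,
# results/permdisp_*.csv, results/nmds_*.csv.

library(traitvolume)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
cfg <- analysis_config(rng_seed = seed, grid_cells_per_axis = 10L)

inp <- read_inputs("results/pool_traits.csv", "results/specimens.csv",
                   "results/community_long.csv", "results/sample_meta.csv")
filt <- filter_rare_and_incomplete(inp$community, inp$traits, cfg)
space <- trait_pcoa(gower_dissim(standardize_traits(filt$traits)),
                    cfg$n_axes)
div <- diversity_table(filt$community, filt$traits, space,
                       trim_alpha = cfg$trim_alpha,
                       cells_per_axis = cfg$grid_cells_per_axis)

dissims <- list(taxonomic = bray_curtis(filt$community),
                functional = functional_dissim(div$ctpds))
for (level in names(dissims)) {
  dd <- dissims[[level]]
  pa <- permanova(dd, filt$community$meta, cfg$n_permutations, seed)
  write.csv(pa, sprintf("results/permanova_%s.csv", level),
            row.names = FALSE)
  pd <- permdisp(dd, filt$community$meta$assemblage, cfg$n_permutations,
                 seed)
  write.csv(data.frame(group = names(pd$group_means),
                       mean_dist_to_median = as.numeric(pd$group_means),
                       f = pd$f, p = pd$p),
            sprintf("results/permdisp_%s.csv", level), row.names = FALSE)
  nm <- nmds(dd, seed = seed)
  write.csv(data.frame(sample_id = rownames(nm$points), nm$points,
                       stress = nm$stress),
            sprintf("results/nmds_%s.csv", level), row.names = FALSE)
  cat(sprintf(
    "%s: assemblage R2 %.2f (p %.3f); PERMDISP means %s; NMDS stress %.3f\n",
    level, pa$r2[pa$term == "assemblage"], pa$p[pa$term == "assemblage"],
    paste(sprintf("%s %.2f", names(pd$group_means), pd$group_means),
          collapse = ", "),
    nm$stress))
}
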