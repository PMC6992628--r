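# traitvolume

Functional-trait analysis of saproxylic beetle assemblages: from raw
trait and abundance tables to trait-probability-density (TPD) functional
diversity, area-restricted null models with standardised effect sizes,
and taxonomic/functional turnover.

## The scientific problem

Two trap types sample different slices of the dead-wood beetle fauna:
hollow emergence traps (HET) seal tree cavities and collect the species
developing inside them, while window traps (WT) intercept the beetles
flying through the surrounding woodland. Comparing the two assemblages
across study areas asks a functional question: do they occupy trait
space differently, and are they assembled by different processes —
environmental **niche filtering** (which narrows trait variation) or
**limiting similarity** (which spaces coexisting species apart)?

The package implements the analysis chain for that question:

- **Trait derivation** — body length; *robustness*, the mean residual of
  five shape measures (pronotum width/length/depth, elytra width, head
  width) each regressed on body length across all specimens, a
  size-independent shape trait; elytra-length ratio; relative eye size;
  trophic guild (5 levels); months active; temperature range of the
  active months.
- **Filters** — dataset-wide singletons/doubletons removed, then species
  missing more than 4 of the 7 traits.
- **Trait space** — Gower dissimilarity over mixed traits (missing
  values tolerated), PCoA, 4 retained axes.
- **TPD diversity** — per-species Gaussian TPDs on a discretised grid
  (Silverman bandwidths, 0.99 trimming); abundance-weighted community
  TPDs; FRic (occupied volume), FEve (overlap with uniform), FDiv
  (abundance far from the centre), relative functional redundancy, and
  the TPD-overlap dissimilarity 1 − Σ min(a, b).
- **Null models** — area-restricted checkerboard swaps preserving sample
  richness and species occupancy; SES = (obs − mean_null)/sd_null for
  FRic and MPD.
- **Turnover** — Bray–Curtis and TPD-overlap sample dissimilarities;
  PERMANOVA (sequential SS: assemblage, area, interaction), PERMDISP
  (distance to group spatial median, Weiszfeld iteration), NMDS.
- **Inference** — Gaussian or Poisson factorial models per response with
  Benjamini–Hochberg control per test family.
- **Synthetic communities** — a generator that reproduces the 69 + 56
  trap design across three areas with plantable assembly rules
  (neutral / filtering / overdispersion), so the whole chain is testable
  without the field data.

## Worked example

```r
library(traitvolume)

sim <- sim_config(rng_seed = 42)      # HET = overdispersion, WT = filtering
d   <- simulate_dataset(sim)
cfg <- analysis_config(n_null_reps = 99, grid_cells_per_axis = 10,
                       rng_seed = 42)

filt  <- filter_rare_and_incomplete(d$community, d$traits, cfg)
space <- trait_pcoa(gower_dissim(standardize_traits(filt$traits)), cfg$n_axes)
div   <- diversity_table(filt$community, filt$traits, space,
                         cells_per_axis = cfg$grid_cells_per_axis)
sf    <- ses_metric("fric", filt$community, space, grid = div$grid,
                    n_reps = cfg$n_null_reps, seed = cfg$rng_seed)

rule <- d$truth$rule[match(sf$sample_id, d$truth$sample_id)]
mean(sf$ses[rule == "filtering"] < 0)       # 0.964
mean(sf$ses[rule == "overdispersion"] > 0)  # 0.986
round(tapply(sf$ses, rule, mean), 2)        # filtering -3.99, overdispersion 1.56
```

The numbers say: 96% of the niche-filtered (window-trap-like) samples
occupy **less** trait volume than their richness-matched null (SES-FRic
< 0, mean −4.0), while 99% of the limiting-similarity (hollow-trap-like)
samples occupy **more** (mean +1.6) — the planted assembly contrast is
recovered sample by sample.

The numbered scripts under `analysis/` run the same chain as a
five-step narrative (simulate → filter/traits → diversity/nulls →
turnover → report), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R 42
Rscript analysis/02_filter_traits.R 42
Rscript analysis/03_diversity_nulls.R 42
Rscript analysis/04_turnover.R 42
Rscript analysis/05_report.R 42
```

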