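---
title: "Trait probability density diversity for saproxylic beetle assemblages: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait probability density diversity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitvolume)
```

## The problem

Saproxylic beetles — species that depend on dead or decaying wood — are
sampled with two complementary trap types: hollow emergence traps (HET)
sealed over tree cavities, and window (flight-intercept) traps (WT) that
catch the mobile fauna of the surrounding woodland. The two trap types
sample different assemblages, and the question this package addresses is
functional: do the two assemblages occupy trait space differently, and do
different assembly processes (environmental niche filtering versus
limiting similarity among competitors) shape them?

`traitvolume` implements the full chain of that analysis as reusable,
tested functions: species-level trait derivation, rare-species and
missing-trait filters, a mixed-type Gower dissimilarity reduced by
principal coordinates analysis (PCoA), trait probability density (TPD)
functional diversity on a discretised trait space, area-restricted
matrix-swap null models with standardised effect sizes (SES), taxonomic
and functional turnover tests, and factorial inference with
false-discovery-rate control. Because the original field data are not
redistributable, the package ships a synthetic-community generator whose
assembly rules are known, so every downstream claim can be checked
against planted truth.

## Traits

Seven traits describe each species:

| trait | units | derivation |
|---|---|---|
| body length | mm | specimen mean |
| robustness | mm (residual) | see below |
| elytra length ratio | — | elytra length / elytra-base-to-abdomen-apex length |
| relative eye size | mm | eye surface / head width |
| trophic guild | 5 levels | predator, xylophagous, saproxylophagous, saprophagous, mycetophagous |
| months active | count 1–12 | distinct months with adult captures, pooled over areas |
| temperature range | °C | max − min monthly temperature over the months × areas where active |

**Robustness** is a size-free shape trait. Each of five shape measures
(pronotum width, length, depth; elytra width; head width) is regressed on
body length across all specimens pooled (one to ten specimens per
species), and a species' robustness is the mean over the five regressions
of its specimens' mean residual. Species with larger shape measures than
expected for their length score positive. The regressions pool specimens
rather than species means because the specimen-level allometry is what
the residual is defined against; averaging residuals within species then
uses however many specimens are available. By construction the trait is
essentially uncorrelated with body length (the package tests enforce
|r| < 0.05 on recoverable cases).

**Counts and ranges as quantitative traits.** Months active is a count
and temperature range a non-negative difference; both enter the Gower
dissimilarity as quantitative variables. Temperature range can be exactly
0 (a species active one month in one area), which is a real value, not a
missing one.

## Filters

Two species-level filters run before any functional analysis, in this
order:

1. species whose **dataset-wide** total abundance is ≤ 2 (singletons and
   doubletons) are removed — phenological and physiological traits cannot
   be measured from one or two captures;
2. of the remainder, species missing more than 4 of the 7 traits are
   removed.

The rare filter uses dataset-wide totals rather than per-assemblage
totals: the filter exists because of measurement feasibility, which
depends on total captures, and a single global count is what a filter
report should state. Filtering is idempotent and conserves individuals
(removed + retained = original), both property-tested.

## Standardisation and trait space

Strictly positive quantitative traits are log-transformed and scaled to
zero mean and unit (population) variance. Robustness (sign-indefinite)
and temperature range (zero-admitting) are z-scaled without the log —
a blanket log-transform is undefined for them. The categorical guild is
left untouched.

Community-weighted means (CWM) are computed on **raw** trait scales, so
that CWM body length is still in mm; standardisation only feeds the
dissimilarity/ordination path. Species missing a trait are dropped from
that trait's CWM with weights renormalised; the guild CWM is the vector
of relative guild abundances and always sums to 1.

Gower dissimilarity (range-normalised quantitative differences, 0/1 guild
mismatch, pair-wise averaged over shared non-missing traits; ranges from
the full filtered table) is computed via `cluster::daisy` and verified
against a brute-force oracle to 1e-12. PCoA (classical scaling of the
double-centred matrix) retains 4 axes by default; negative eigenvalues
are dropped from both numerator and denominator of the variance fraction
— no Cailliez/Lingoes correction, because corrected eigenvalues change
the variance-explained bookkeeping without changing the retained
configuration at this problem scale.

## TPD functional diversity

Species' trait probability densities are product Gaussians centred on
their PCoA scores, evaluated at the cell centres of a regular grid,
normalised to sum 1, trimmed to the smallest set of highest-density cells
holding `trim_alpha = 0.99` of mass, and renormalised. Bandwidths default
to Silverman's rule of thumb (`stats::bw.nrd0`) per axis over all species
scores: the published tables give species means, not specimen clouds, so
a deterministic rule-of-thumb kernel is the honest choice; bandwidths are
a config argument for sensitivity work. The grid spans each axis's score
range ± 3 bandwidths; the default resolution is 15 cells per axis with a
hard cap of 10^6 cells.

Community TPDs are abundance-weighted mixtures of the present species'
TPDs. From the (re-trimmed) community TPD:

- **FRic** = number of retained cells × cell volume (occupied trait-space
  volume);
- **FEve** = Σ min(p, 1/N_occ) over occupied cells — overlap with the
  uniform density on the occupied support;
- **FDiv** = (Δd + d̄)/(Δ|d| + d̄), where d are occupied-cell distances to
  the unweighted centroid of occupied cell centres, d̄ their mean, and
  Δd, Δ|d| the abundance-weighted mean (absolute) deviations. The
  unweighted-support centre-of-gravity adaptation is our choice for a
  gridded density; it is isolated in one function and checked by direct
  cell-sum oracles;
- **relative redundancy** = (Σ p(cell)·n(cell) − 1)/(S − 1), with n(cell)
  the number of present species whose trimmed TPD covers the cell —
  0 when all species are functionally disjoint, 1 when all S coincide;
- the **overlap dissimilarity** between two TPDs is 1 − Σ min(a, b).

All densities are unit-sum to 1e-9 (tested); FRic of a smooth 1-D test
community changes by < 10% when the grid is refined twofold (tested at
1-D and 2-D).

## Null models and standardised effect sizes

FRic correlates strongly with species richness, so observed values are
compared with a matrix-swap null model on the presence/absence matrix:
sequential 2×2 checkerboard swaps that preserve every sample's richness
and every species' occupancy, applied **independently within each study
area** so species never move between areas. The chain burns in for 20×
the number of presences and emits one matrix every 20× the number of
presences (the swap inner loop is compiled, so heavy thinning is cheap);
the attempt count per batch is Poisson-randomised, which keeps the chain
aperiodic on degenerate submatrices (a lone 2×2 checkerboard would
otherwise toggle deterministically). The heavy thinning is deliberate:
at the acceptance probabilities typical of matrices this dense,
light thinning leaves autocorrelation between consecutive emitted
matrices that biases the SES denominator downward and inflates the
|SES| > 1.96 rate on neutral data; 20× restores nominal calibration at
99 replicates (the package's scaled-down test setting; the full-study
default is 500 replicates).

SES = (observed − null mean)/null sd, with the sample standard deviation.
Null communities re-use the observed sample's abundance vector assigned
to the null species set in decreasing-abundance order onto a random
permutation (rank shuffle); presence-based MPD ignores the weights, and
FRic depends on them only through trimming.

MPD (mean pairwise distance) defaults to the unweighted form over all
co-occurring pairs, with distances taken in the retained PCoA space for
consistency with the TPD space; an abundance-weighted form and raw-Gower
distances are available as options.

## Turnover and ordination

Taxonomic dissimilarity between samples is Bray–Curtis on counts;
functional dissimilarity is the TPD overlap complement, sample-pairwise.
PERMANOVA (vegan's `adonis2`) partitions either matrix by assemblage,
area and their interaction with sequential sums of squares in that fixed
order and free permutation of rows. PERMDISP embeds the matrix by PCoA
(imaginary axes handled by the signed squared-distance convention),
computes each sample's distance to its group's spatial median by
Weiszfeld iterative reweighting run to machine precision, and tests
equality of group mean distances by a permutation F. NMDS (vegan's
`metaMDS` on the supplied distances, 20 random starts by default)
visualises the same matrices at the sample level; the Kruskal stress-1 of
the accepted run is reported.

## The synthetic generator

The generator emulates the study design — 69 HET and 56 WT trap-year
samples split 13/29/27 and 14/22/20 across three areas — with known
assembly rules per assemblage. Its defaults are the package's documented
study conditions:

- **pool**: 180 core species (plus a 15% injected-rare pool that yields
  dataset-wide singletons/doubletons, removed by the filters), body
  length log-normal (meanlog 1.6, sdlog 0.7 — roughly 2–25 mm), elytra
  ratio near 1, relative eye size log-normal, 1–12 active months with
  thermal ranges widening with the activity period, guilds multinomial;
- **trait conservatism**: species belong to congener-like clumps (mean
  size 3) holding 30% of each trait's variation within clumps. Real trait
  tables are clumpy because congeners share morphology; a pool with
  independent species would understate the kernel overlap that random
  co-occurrence produces;
- **robustness**: a planted per-species offset (sd 0.8 mm) added to each
  shape measure's allometric prediction, with 5% log-normal measurement
  noise; `derive_robustness` recovers it with rank correlation > 0.9
  (tested);
- **assembly**: *neutral* samples draw species uniformly; *filtering*
  samples (WT default) weight species by a Gaussian kernel of width
  σ_f = 0.35 around a sample-specific optimum in the standardised
  quantitative-trait space; *overdispersion* samples (HET default) build
  a set with minimum pairwise spacing δ = 1.8, drawing each next species
  among the still-eligible ones with weight increasing steeply in its
  distance to the accepted set — a stochastic farthest-point rule, the
  usual stylisation of limiting similarity. Guild never enters the
  assembly rules, so categorical CWM contrasts stay unconfounded;
- **richness** per sample is Poisson (mean 28) floored at 3 and capped at
  32, the cap keeping the overdispersion rule seatable; **abundances**
  are log-normal (meanlog 1, sdlog 1.2) rounded with floor 1, giving
  realistic steep rank-abundance curves;
- **missingness**: 3% of measured quantitative cells (robustness, elytra
  ratio, eye size, temperature range) are masked; body length, months
  and guild are always present, as they would be for any identifiable
  species;
- one integer seed drives everything; per-sample sub-streams are derived
  deterministically from it, so outputs are bit-reproducible.

What the generator does **not** emulate: spatial structure within areas,
phenology (trap-by-month matrices), detection bias, abundance-dependent
trait measurement error, or guild–morphology correlations. Passing tests
on synthetic data therefore demonstrate that the estimators and null
models behave correctly under known assembly rules at realistic sizes —
not that any particular field dataset satisfies those rules.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run the full design (125
samples, 180-species core pool) with 99 null replicates and a 10-cell
4-axis grid; the full-study settings (500 replicates, 15 cells) are the
config defaults and scale linearly. Degenerate inputs are handled
explicitly: zero-variance traits refuse to scale; a species pair sharing
no non-missing traits is an error naming the pair; FDiv is undefined
(NA with warning) on a single occupied cell; SES is NA when the null has
zero spread; an area submatrix with no swappable checkerboard passes
through with a warning. Ties in trimming are resolved by densest-first
ordering; the trim keeps the smallest cell set reaching 99% of mass.

## Known limitations

- Species TPDs are Gaussians at species mean scores; intraspecific trait
  variation is not modelled (the published tables do not support it).
- FDiv's grid adaptation (unweighted-support centroid) is one of several
  defensible definitions; comparisons across packages should use the
  same definition.
- The coverage-based completeness estimator is the ACE-type formula with
  a rare-group cutoff of 10; Chao1 is used only as the zero-coverage
  fallback. Other software may label different estimators "coverage".
- PERMANOVA uses free permutation; restricted (within-area) permutation
  schemes are not implemented.
- The equivalence of observed and swap-null communities holds
  conditionally on the margins; with very sparse areas the null can be
  degenerate, and the package warns rather than resamples.
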