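# End-to-end orchestration: filters -> trait space -> TPD metrics ->
# null models -> turnover -> report.

#' Per-sample functional and taxonomic diversity table
#'
#' Computes, for every sample: richness, Gini-Simpson equivalent number,
#' guild Shannon diversity, FRic, FEve, FDiv, relative redundancy and MPD.
#'
#' @param community a [community_matrix()] (filtered).
#' @param traits trait table for the community's species (for guilds).
#' @param space a \code{trait_space} over the same species.
#' @param grid optional [tpd_grid()]; built from the space when NULL.
#' @param trim_alpha TPD trimming mass.
#' @param cells_per_axis grid resolution when \code{grid} is NULL.
#' @return list with \code{table} (per-sample indices + metadata),
#'   \code{ctpds} (cells x samples community TPD matrix), \code{grid} and
#'   \code{species_tpds}.
#' @export
diversity_table <- function(community, traits, space, grid = NULL,
                            trim_alpha = 0.99, cells_per_axis = 15L) {
  abund <- community$abund
  scores <- space$scores[colnames(abund), , drop = FALSE]
  if (is.null(grid)) grid <- tpd_grid(scores,
                                      cells_per_axis = cells_per_axis)
  tpds <- species_tpd(scores, grid, trim_alpha)
  guilds <- stats::setNames(as.character(traits$guild), traits$species_id)
  n <- nrow(abund)
  ctpds <- matrix(0, grid$n_cells, n,
                  dimnames = list(NULL, rownames(abund)))
  tab <- community$meta
  tab$richness <- NA_real_
  tab$simpson_equivalent <- NA_real_
  tab$guild_shannon <- NA_real_
  tab$fric <- NA_real_
  tab$feve <- NA_real_
  tab$fdiv <- NA_real_
  tab$redundancy <- NA_real_
  tab$mpd <- NA_real_
  for (j in seq_len(n)) {
    w <- abund[j, ]
    rs <- richness_simpson(w)
    tab$richness[j] <- rs$richness
    tab$simpson_equivalent[j] <- rs$simpson_equivalent
    tab$guild_shannon[j] <- guild_shannon(w, guilds)
    p <- community_tpd(tpds, w)
    pt <- tpd_trim(p, trim_alpha)
    ctpds[, j] <- pt
    tab$fric[j] <- tpd_fric(p, grid, trim_alpha)
    tab$feve[j] <- tpd_feve(pt)
    tab$fdiv[j] <- tpd_fdiv(pt, grid)
    tab$redundancy[j] <- tpd_redundancy(pt, tpds, w)
    tab$mpd[j] <- mpd(w, scores)
  }
  list(table = tab, ctpds = ctpds, grid = grid, species_tpds = tpds)
}

#' Run the full analysis pipeline
#'
#' Applies the species filters, standardises traits, builds the Gower/PCoA
#' trait space, computes community-weighted means (on raw trait scales),
#' per-sample diversity indices, SES-FRic and SES-MPD under the
#' area-restricted null, taxonomic and functional turnover tests, and the
#' final report tables.
#'
#' @param traits,specimens,community validated input tables (see
#'   [read_inputs()]); \code{specimens} may be NULL when the trait table
#'   already carries robustness.
#' @param config an [analysis_config()].
#' @return list with the filtered data, \code{filter_report},
#'   \code{space}, \code{cwm}, \code{diversity} (per-sample indices
#'   including SES columns), \code{completeness} (per assemblage),
#'   \code{turnover} (PERMANOVA/PERMDISP/NMDS for both dissimilarities),
#'   and \code{report}.
#' @export
run_pipeline <- function(traits, community, specimens = NULL,
                         config = analysis_config()) {
  filt <- filter_rare_and_incomplete(community, traits, config)
  community <- filt$community
  traits <- filt$traits

  comp <- lapply(split(seq_len(nrow(community$abund)),
                       community$meta$assemblage),
                 function(rows) {
                   completeness(colSums(community$abund[rows, ,
                                                        drop = FALSE]),
                                config$rare_cutoff)
                 })

  cwm_table <- cwm(community, traits)
  std <- standardize_traits(traits)
  dissim <- gower_dissim(std)
  space <- trait_pcoa(dissim, config$n_axes)

  div <- diversity_table(community, traits, space,
                         trim_alpha = config$trim_alpha,
                         cells_per_axis = config$grid_cells_per_axis)
  tab <- div$table
  for (m in c("fric", "mpd")) {
    s <- ses_metric(m, community, space, grid = div$grid,
                    n_reps = config$n_null_reps,
                    trim_alpha = config$trim_alpha,
                    seed = config$rng_seed)
    tab[[paste0("ses_", m)]] <- s$ses
  }

  d_tax <- bray_curtis(community)
  d_fun <- functional_dissim(div$ctpds)
  groups <- community$meta$assemblage
  turnover <- list(
    taxonomic = list(
      dissim = d_tax,
      permanova = permanova(d_tax, community$meta,
                            config$n_permutations, config$rng_seed),
      permdisp = permdisp(d_tax, groups, config$n_permutations,
                          config$rng_seed),
      nmds = nmds(d_tax, seed = config$rng_seed)),
    functional = list(
      dissim = d_fun,
      permanova = permanova(d_fun, community$meta,
                            config$n_permutations, config$rng_seed),
      permdisp = permdisp(d_fun, groups, config$n_permutations,
                          config$rng_seed),
      nmds = nmds(d_fun, seed = config$rng_seed)))

  report <- build_report(cwm_table, tab, config)
  list(community = community, traits = traits,
       filter_report = filt$report, completeness = comp, space = space,
       cwm = cwm_table, diversity = tab, turnover = turnover,
       report = report)
}
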