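# Shared domain types, input readers/validators, and species-level filters.

#' Trophic guild levels recognised throughout the package
#'
#' The five guilds used to classify saproxylic beetles: predators,
#' xylophagous (wood-eating), saproxylophagous (decaying-wood),
#' saprophagous (decaying organic matter) and mycetophagous (fungus-eating)
#' species.
#' @export
GUILD_LEVELS <- c("predator", "xylophagous", "saproxylophagous",
                  "saprophagous", "mycetophagous")

#' Names of the quantitative trait columns
#'
#' Six quantitative traits plus the categorical \code{guild} make up the
#' seven-trait universe used by the filters and the Gower dissimilarity.
#' \code{months_active} is a count (1-12) and \code{temperature_range} a
#' difference in degrees Celsius; both are treated as quantitative.
#' @export
QUANT_TRAITS <- c("body_length", "robustness", "ratio_elytra", "eye_size",
                  "months_active", "temperature_range")

#' All trait columns (quantitative traits plus guild)
#' @export
ALL_TRAITS <- c(QUANT_TRAITS, "guild")

#' Validate a species-by-trait table
#'
#' Checks the structural invariants of a trait table: unique species ids,
#' guild levels drawn from [GUILD_LEVELS], positive body lengths and
#' months-active counts in 1-12 where present. Missing values (NA) are
#' allowed in any trait cell.
#'
#' @param traits data.frame with column \code{species_id} and the columns in
#'   [ALL_TRAITS]; an optional \code{family} column is carried along for
#'   reporting only.
#' @return the validated data.frame, invisibly classed \code{trait_table}.
#' @export
validate_trait_table <- function(traits) {
  stopifnot(is.data.frame(traits))
  required <- c("species_id", ALL_TRAITS)
  missing_cols <- setdiff(required, names(traits))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(traits$species_id)) {
    stop("species_id values must be unique; duplicated: ",
         paste(unique(traits$species_id[duplicated(traits$species_id)]),
               collapse = ", "))
  }
  bad_guild <- setdiff(stats::na.omit(unique(as.character(traits$guild))),
                       GUILD_LEVELS)
  if (length(bad_guild) > 0L) {
    stop("invalid guild level(s): ", paste(bad_guild, collapse = ", "),
         "; allowed: ", paste(GUILD_LEVELS, collapse = ", "))
  }
  ma <- traits$months_active
  if (any(!is.na(ma) & (ma < 1 | ma > 12))) {
    stop("months_active must lie in [1, 12] where present")
  }
  bl <- traits$body_length
  if (any(!is.na(bl) & bl <= 0)) {
    stop("body_length must be strictly positive where present")
  }
  class(traits) <- unique(c("trait_table", class(traits)))
  invisible(traits)
}

#' Validate a per-specimen morphometric table
#'
#' @param specimens data.frame with \code{species_id} and strictly positive
#'   measures in mm: \code{body_length}, \code{pronotum_width},
#'   \code{pronotum_length}, \code{pronotum_depth}, \code{elytra_width},
#'   \code{elytra_length}, \code{head_width},
#'   \code{abdomen_from_elytra_base_length}, and \code{eye_surface} (mm^2).
#'   One to ten specimens per species.
#' @return the validated data.frame, invisibly.
#' @export
validate_specimen_table <- function(specimens) {
  stopifnot(is.data.frame(specimens))
  required <- c("species_id", SPECIMEN_MEASURES)
  missing_cols <- setdiff(required, names(specimens))
  if (length(missing_cols) > 0L) {
    stop("specimen table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  vals <- as.matrix(specimens[, SPECIMEN_MEASURES])
  if (any(!is.na(vals) & vals <= 0)) {
    stop("all specimen measures must be strictly positive where present")
  }
  n_per <- table(specimens$species_id)
  if (any(n_per > 10L)) {
    stop("more than 10 specimens for species: ",
         paste(names(n_per)[n_per > 10L], collapse = ", "))
  }
  invisible(specimens)
}

#' Measure columns expected in a specimen table
#' @export
SPECIMEN_MEASURES <- c("body_length", "pronotum_width", "pronotum_length",
                       "pronotum_depth", "elytra_width", "elytra_length",
                       "head_width", "abdomen_from_elytra_base_length",
                       "eye_surface")

#' Construct a sample-by-species community matrix with metadata
#'
#' @param abund numeric matrix of non-negative integer counts, samples in
#'   rows (rownames = sample ids), species in columns (colnames = species
#'   ids).
#' @param meta data.frame with columns \code{sample_id},
#'   \code{assemblage} (\code{"HET"} or \code{"WT"}) and \code{area}
#'   (\code{"Azaba"}, \code{"Cabaneros"} or \code{"Quilamas"}, or any other
#'   consistent area labels), one row per sample.
#' @return object of class \code{community_matrix}: a list with elements
#'   \code{abund} and \code{meta}, rows of \code{abund} aligned with
#'   \code{meta$sample_id}.
#' @export
community_matrix <- function(abund, meta) {
  abund <- as.matrix(abund)
  stopifnot(is.numeric(abund), is.data.frame(meta))
  if (is.null(rownames(abund)) || is.null(colnames(abund))) {
    stop("abundance matrix needs sample rownames and species colnames")
  }
  if (any(abund < 0)) stop("abundance counts must be non-negative")
  if (any(abund != round(abund))) stop("abundance counts must be integers")
  required <- c("sample_id", "assemblage", "area")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!setequal(rownames(abund), meta$sample_id)) {
    stop("metadata sample_id set must match abundance matrix rownames")
  }
  meta <- meta[match(rownames(abund), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(abund = abund, meta = meta), class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix:", nrow(x$abund), "samples x", ncol(x$abund),
      "species;", sum(x$abund), "individuals\n")
  print(table(x$meta$assemblage, x$meta$area))
  invisible(x)
}

#' Analysis configuration with package defaults
#'
#' @param n_axes number of PCoA axes retained for the trait space.
#' @param n_null_reps null-model replicates for standardised effect sizes.
#' @param n_permutations permutations for PERMANOVA/PERMDISP.
#' @param trim_alpha probability mass retained when trimming trait
#'   probability densities, in (0, 1).
#' @param grid_cells_per_axis grid resolution of the discretised trait space.
#' @param cell_cap hard cap on the total number of grid cells.
#' @param rng_seed integer seed for all stochastic steps.
#' @param rare_max_total species with dataset-wide total abundance at or
#'   below this value are dropped (2 removes singletons and doubletons).
#' @param max_missing_traits species missing more than this many of the
#'   seven traits are dropped.
#' @param rare_cutoff abundance at or below which a species counts as
#'   "rare" in the coverage-based richness estimator.
#' @return a classed list of settings.
#' @export
analysis_config <- function(n_axes = 4L, n_null_reps = 500L,
                            n_permutations = 999L, trim_alpha = 0.99,
                            grid_cells_per_axis = 15L, cell_cap = 1e6,
                            rng_seed = 1L, rare_max_total = 2L,
                            max_missing_traits = 4L, rare_cutoff = 10L) {
  cfg <- list(n_axes = as.integer(n_axes),
              n_null_reps = as.integer(n_null_reps),
              n_permutations = as.integer(n_permutations),
              trim_alpha = trim_alpha,
              grid_cells_per_axis = as.integer(grid_cells_per_axis),
              cell_cap = cell_cap,
              rng_seed = as.integer(rng_seed),
              rare_max_total = as.integer(rare_max_total),
              max_missing_traits = as.integer(max_missing_traits),
              rare_cutoff = as.integer(rare_cutoff))
  counts <- c(cfg$n_axes, cfg$n_null_reps, cfg$n_permutations,
              cfg$grid_cells_per_axis, cfg$rare_cutoff)
  if (any(counts <= 0L)) stop("all count settings must be positive")
  if (cfg$trim_alpha <= 0 || cfg$trim_alpha >= 1) {
    stop("trim_alpha must lie in (0, 1)")
  }
  class(cfg) <- "analysis_config"
  cfg
}

#' Read and validate the three input tables
#'
#' Reads delimited text (CSV by default) for the trait, specimen and
#' community tables, validates each, and checks referential integrity: every
#' species in the community matrix must appear in the trait table.
#'
#' @param traits_path,specimens_path path to the species-by-trait and
#'   per-specimen CSV files.
#' @param community_path path to a long-format community CSV with columns
#'   \code{sample_id}, \code{species_id}, \code{abundance}.
#' @param meta_path path to the per-sample metadata CSV with columns
#'   \code{sample_id}, \code{assemblage}, \code{area}.
#' @param sep field separator passed to [utils::read.csv()].
#' @return list with elements \code{traits}, \code{specimens},
#'   \code{community} (a [community_matrix()]).
#' @export
read_inputs <- function(traits_path, specimens_path, community_path,
                        meta_path, sep = ",") {
  for (p in c(traits_path, specimens_path, community_path, meta_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  traits <- utils::read.csv(traits_path, sep = sep,
                            stringsAsFactors = FALSE)
  traits <- validate_trait_table(traits)
  specimens <- utils::read.csv(specimens_path, sep = sep,
                               stringsAsFactors = FALSE)
  specimens <- validate_specimen_table(specimens)
  comm_long <- utils::read.csv(community_path, sep = sep,
                               stringsAsFactors = FALSE)
  required <- c("sample_id", "species_id", "abundance")
  missing_cols <- setdiff(required, names(comm_long))
  if (length(missing_cols) > 0L) {
    stop("community table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  meta <- utils::read.csv(meta_path, sep = sep, stringsAsFactors = FALSE)
  abund <- stats::xtabs(abundance ~ sample_id + species_id, data = comm_long)
  abund <- matrix(as.numeric(abund), nrow = nrow(abund),
                  dimnames = dimnames(abund))
  community <- community_matrix(abund, meta)
  orphans <- setdiff(colnames(community$abund), traits$species_id)
  if (length(orphans) > 0L) {
    stop("species in community matrix absent from trait table: ",
         paste(orphans, collapse = ", "))
  }
  list(traits = traits, specimens = specimens, community = community)
}

#' Remove rare and trait-incomplete species
#'
#' Two sequential species-level filters applied before any functional
#' analysis: (1) species whose dataset-wide total abundance is at or below
#' \code{rare_max_total} (default 2: singletons and doubletons) are removed,
#' because phenological and physiological traits cannot be measured from so
#' few captures; (2) of the remainder, species missing more than
#' \code{max_missing_traits} (default 4) of the seven traits are removed.
#'
#' @param community a [community_matrix()].
#' @param traits a validated trait table covering the community's species.
#' @param config an [analysis_config()]; \code{rare_max_total} and
#'   \code{max_missing_traits} are used.
#' @return list with the filtered \code{community} and \code{traits} and a
#'   \code{report} list: species/individual counts removed at each step and
#'   retained totals (plus family counts when a \code{family} column is
#'   present).
#' @export
filter_rare_and_incomplete <- function(community, traits,
                                       config = analysis_config()) {
  stopifnot(inherits(community, "community_matrix"))
  abund <- community$abund
  traits <- traits[match(colnames(abund), traits$species_id), , drop = FALSE]
  totals <- colSums(abund)
  rare <- totals <= config$rare_max_total
  n_missing <- rowSums(is.na(traits[, ALL_TRAITS, drop = FALSE]))
  incomplete <- !rare & n_missing > config$max_missing_traits
  keep <- !rare & !incomplete
  if (!any(keep)) stop("no species survive filters")
  report <- list(
    n_rare_removed = sum(rare),
    n_incomplete_removed = sum(incomplete),
    individuals_rare_removed = sum(totals[rare]),
    individuals_incomplete_removed = sum(totals[incomplete]),
    n_species_retained = sum(keep),
    individuals_retained = sum(totals[keep]),
    n_species_original = length(totals),
    individuals_original = sum(totals))
  if ("family" %in% names(traits)) {
    report$n_families_retained <-
      length(unique(stats::na.omit(traits$family[keep])))
  }
  abund <- abund[, keep, drop = FALSE]
  nonempty <- rowSums(abund) > 0
  out_comm <- community_matrix(abund[nonempty, , drop = FALSE],
                               community$meta[nonempty, , drop = FALSE])
  list(community = out_comm,
       traits = traits[keep, , drop = FALSE],
       report = report)
}
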