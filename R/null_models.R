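#' @useDynLib traitvolume, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Area-restricted matrix-swap null model and standardised effect sizes.
#
# The null randomises the binary sample x species matrix by sequential 2x2
# checkerboard swaps, independently within each study area, so row totals
# (sample richness) and column totals (per-species occupancy within the
# area) are preserved and species never move between areas.

# attempt about `n_attempts` checkerboard swaps on a binary matrix (the
# inner loop is compiled; see src/swap.cpp); the count is
# Poisson-randomised so the chain cannot be periodic on tiny matrices
# (a lone 2x2 checkerboard would toggle on every attempt)
swap_attempts <- function(m, n_attempts) {
  n_attempts <- stats::rpois(1L, n_attempts)
  storage.mode(m) <- "integer"
  .swap_attempts_cpp(m, n_attempts)
}

#' Area-restricted checkerboard-swap null matrices
#'
#' Generates \code{n_reps} randomised presence/absence matrices. Within
#' each area's submatrix, sequential 2x2 checkerboard swaps preserve all
#' row and column totals; a burn-in of \code{burn_in_mult} times the number
#' of presences is discarded, then one matrix is emitted every
#' \code{thin_mult} times the number of presences. Areas with no swappable
#' checkerboard (fewer than 2 samples or species) are passed through
#' unchanged with a warning.
#'
#' @param presence binary sample x species matrix (dimnames required).
#' @param areas character vector of area labels, one per sample (row).
#' @param n_reps number of null matrices to emit.
#' @param burn_in_mult,thin_mult burn-in and thinning multipliers on the
#'   number of presences.
#' @param seed integer seed.
#' @return list of \code{n_reps} binary matrices with an
#'   \code{"accepted"} attribute (total accepted swaps per area).
#' @export
restricted_swap <- function(presence, areas, n_reps = 500L,
                            burn_in_mult = 20, thin_mult = 20, seed = 1L) {
  presence <- (as.matrix(presence) > 0) * 1L
  stopifnot(length(areas) == nrow(presence))
  set.seed(as.integer(seed))
  area_rows <- split(seq_len(nrow(presence)), areas)
  reps <- vector("list", n_reps)
  accepted <- stats::setNames(numeric(length(area_rows)), names(area_rows))
  current <- presence
  state <- lapply(area_rows, function(rows) {
    presence[rows, , drop = FALSE]
  })
  for (a in names(area_rows)) {
    sub <- state[[a]]
    ones <- sum(sub)
    if (nrow(sub) < 2L || ones == 0L) {
      warning("area ", a, " has no swappable checkerboard; ",
              "null is degenerate there")
      next
    }
    sub <- swap_attempts(sub, as.integer(ceiling(burn_in_mult * ones)))
    accepted[a] <- accepted[a] + attr(sub, "accepted")
    state[[a]] <- sub
  }
  for (r in seq_len(n_reps)) {
    for (a in names(area_rows)) {
      sub <- state[[a]]
      ones <- sum(sub)
      if (nrow(sub) < 2L || ones == 0L) next
      sub <- swap_attempts(sub, as.integer(ceiling(thin_mult * ones)))
      accepted[a] <- accepted[a] + attr(sub, "accepted")
      state[[a]] <- sub
      current[area_rows[[a]], ] <- sub
    }
    out <- current
    attr(out, "accepted") <- accepted
    reps[[r]] <- out
  }
  reps
}

#' Standardised effect size
#'
#' SES = (observed - mean(null)) / sd(null), with the sample (n-1) standard
#' deviation. NA with a warning when the null draws have zero spread.
#'
#' @param observed observed metric value (scalar or vector over samples).
#' @param nulls matrix of null draws, replicates in columns (or a vector
#'   for a single sample).
#' @return data.frame with observed, null mean, null sd and SES per sample.
#' @export
ses <- function(observed, nulls) {
  if (is.vector(nulls)) nulls <- matrix(nulls, nrow = 1L)
  if (ncol(nulls) < 2L) stop("need at least 2 null draws")
  null_mean <- rowMeans(nulls, na.rm = TRUE)
  null_sd <- apply(nulls, 1, stats::sd, na.rm = TRUE)
  out <- data.frame(observed = observed, null_mean = null_mean,
                    null_sd = null_sd,
                    ses = (observed - null_mean) / null_sd)
  if (any(!is.na(null_sd) & null_sd == 0)) {
    warning("zero null standard deviation; SES set to NA")
    out$ses[null_sd == 0] <- NA_real_
  }
  out
}

# re-assign one observed abundance vector to a null species set:
# decreasing observed counts onto a random permutation of the null set
rank_shuffle_abund <- function(obs_abund, null_species) {
  counts <- sort(obs_abund[obs_abund > 0], decreasing = TRUE)
  perm <- sample(null_species)
  stats::setNames(counts[seq_along(perm)], perm)
}

#' Standardised effect sizes for FRic or MPD under the area-restricted null
#'
#' Recomputes the chosen metric for every sample on every null replicate
#' and returns per-sample SES. Null communities keep each sample's observed
#' abundance distribution, re-assigned to the null species set by rank
#' shuffle (largest observed count to a random null species, and so on);
#' presence-based MPD ignores the weights.
#'
#' @param metric \code{"fric"} or \code{"mpd"}.
#' @param community a [community_matrix()].
#' @param space a \code{trait_space} covering the community's species.
#' @param grid optional [tpd_grid()] (built from \code{space} when NULL;
#'   required settings come from \code{cells_per_axis}).
#' @param n_reps null replicates.
#' @param trim_alpha TPD trimming mass (FRic only).
#' @param cells_per_axis grid resolution when \code{grid} is NULL.
#' @param seed integer seed governing swaps and rank shuffles.
#' @return data.frame per sample: metadata, observed, null mean/sd, SES.
#' @export
ses_metric <- function(metric = c("fric", "mpd"), community, space,
                       grid = NULL, n_reps = 500L, trim_alpha = 0.99,
                       cells_per_axis = 15L, seed = 1L) {
  metric <- match.arg(metric)
  abund <- community$abund
  scores <- space$scores
  missing_sp <- setdiff(colnames(abund), rownames(scores))
  if (length(missing_sp) > 0L) {
    stop("species without trait-space scores: ",
         paste(missing_sp, collapse = ", "))
  }
  scores <- scores[colnames(abund), , drop = FALSE]
  n_samp <- nrow(abund)
  if (metric == "fric") {
    if (is.null(grid)) grid <- tpd_grid(scores,
                                        cells_per_axis = cells_per_axis)
    tpds <- species_tpd(scores, grid, trim_alpha)
    metric_fun <- function(w) {
      tpd_fric(community_tpd(tpds, w), grid, trim_alpha)
    }
  } else {
    dmat <- as.matrix(stats::dist(scores))
    metric_fun <- function(w) mpd(w, dist_matrix = dmat)
  }
  observed <- vapply(seq_len(n_samp), function(j) {
    metric_fun(abund[j, ])
  }, numeric(1))
  nulls_list <- restricted_swap(abund, community$meta$area,
                                n_reps = n_reps, seed = seed)
  set.seed(sub_seed(seed, 2L))
  null_vals <- matrix(NA_real_, n_samp, n_reps)
  species <- colnames(abund)
  for (r in seq_len(n_reps)) {
    pres <- nulls_list[[r]]
    for (j in seq_len(n_samp)) {
      null_sp <- species[pres[j, ] > 0]
      shuffled <- rank_shuffle_abund(abund[j, ], null_sp)
      w <- stats::setNames(numeric(length(species)), species)
      w[names(shuffled)] <- shuffled
      null_vals[j, r] <- metric_fun(w)
    }
  }
  res <- ses(observed, null_vals)
  cbind(community$meta, res)
}
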