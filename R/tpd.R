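# Trait probability densities on a discretised trait space and the TPD
# family of functional diversity metrics (FRic, FEve, FDiv, redundancy,
# overlap dissimilarity).
#
# Species TPDs are Gaussians centred on the species' PCoA scores with
# per-axis Silverman bandwidths; community TPDs are abundance-weighted
# mixtures. All densities are discrete probability vectors over the grid
# cells (they sum to 1), trimmed to the highest-density region holding
# trim_alpha of the mass and renormalised.

#' Build a discretisation grid over a trait space
#'
#' Per axis, bounds span the species scores plus three bandwidths on either
#' side, divided into \code{cells_per_axis} equal cells. The default
#' bandwidth per axis is Silverman's rule of thumb ([stats::bw.nrd0()])
#' over all species scores on that axis.
#'
#' @param space a \code{trait_space} (or any matrix-like of species scores).
#' @param cells_per_axis cells per axis (total cells =
#'   \code{cells_per_axis ^ n_axes}).
#' @param bandwidths optional numeric vector of per-axis kernel bandwidths;
#'   must be positive.
#' @param cell_cap error if the total cell count exceeds this cap.
#' @return object of class \code{tpd_grid}: per-axis bounds, cell centres,
#'   widths, bandwidths, the cell-to-axis index matrix and the cell volume.
#' @export
tpd_grid <- function(space, cells_per_axis = 15L, bandwidths = NULL,
                     cell_cap = 1e6) {
  scores <- if (inherits(space, "trait_space")) space$scores else
    as.matrix(space)
  k <- ncol(scores)
  if (k < 1L) stop("need at least one trait axis")
  if (is.null(bandwidths)) {
    bandwidths <- apply(scores, 2, stats::bw.nrd0)
  }
  if (length(bandwidths) == 1L) bandwidths <- rep(bandwidths, k)
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  n_cells <- as.numeric(cells_per_axis)^k
  if (n_cells > cell_cap) {
    stop("grid of ", format(n_cells, big.mark = ","),
         " cells exceeds the cap of ", format(cell_cap, big.mark = ","),
         "; reduce cells_per_axis or the number of axes")
  }
  lo <- apply(scores, 2, min) - 3 * bandwidths
  hi <- apply(scores, 2, max) + 3 * bandwidths
  widths <- (hi - lo) / cells_per_axis
  centers <- lapply(seq_len(k), function(a) {
    lo[a] + (seq_len(cells_per_axis) - 0.5) * widths[a]
  })
  idx <- arrayInd(seq_len(n_cells), rep(as.integer(cells_per_axis), k))
  structure(list(cells_per_axis = as.integer(cells_per_axis),
                 n_axes = k, lower = lo, upper = hi, widths = widths,
                 centers = centers, bandwidths = bandwidths, idx = idx,
                 n_cells = as.integer(n_cells),
                 cell_volume = prod(widths)),
            class = "tpd_grid")
}

#' Coordinates of grid cells
#'
#' @param grid a [tpd_grid()].
#' @param cells integer cell indices (default all).
#' @return matrix of cell-centre coordinates, one row per cell.
#' @export
grid_cell_coords <- function(grid, cells = seq_len(grid$n_cells)) {
  m <- vapply(seq_len(grid$n_axes), function(a) {
    grid$centers[[a]][grid$idx[cells, a]]
  }, numeric(length(cells)))
  matrix(m, nrow = length(cells), ncol = grid$n_axes)
}

#' Trim a discrete density to its highest-density region
#'
#' Keeps the smallest set of highest-density cells holding \code{alpha} of
#' the total mass, zeroes the rest and renormalises to sum 1.
#'
#' @param p non-negative density vector over grid cells.
#' @param alpha mass to retain, in (0, 1].
#' @return trimmed, renormalised density vector.
#' @export
tpd_trim <- function(p, alpha = 0.99) {
  p <- p / sum(p)
  ord <- order(p, decreasing = TRUE)
  n_keep <- which(cumsum(p[ord]) >= alpha - 1e-12)[1]
  out <- numeric(length(p))
  keep <- ord[seq_len(n_keep)]
  out[keep] <- p[keep]
  out / sum(out)
}

#' Species trait probability densities
#'
#' Each species' TPD is a product-Gaussian centred on its axis scores with
#' per-axis standard deviation equal to the grid bandwidth, evaluated at
#' cell centres, normalised to sum 1, trimmed at \code{trim_alpha} and
#' renormalised.
#'
#' @param space a \code{trait_space}.
#' @param grid a [tpd_grid()] built over the same space.
#' @param trim_alpha mass retained when trimming.
#' @param bandwidths optional per-axis kernel standard deviations; defaults
#'   to the grid's bandwidths.
#' @return matrix of densities, cells x species (columns named by species).
#' @export
species_tpd <- function(space, grid, trim_alpha = 0.99,
                        bandwidths = grid$bandwidths) {
  scores <- if (inherits(space, "trait_space")) space$scores else
    as.matrix(space)
  stopifnot(ncol(scores) == grid$n_axes)
  if (length(bandwidths) == 1L) bandwidths <- rep(bandwidths, grid$n_axes)
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  n_sp <- nrow(scores)
  out <- matrix(0, grid$n_cells, n_sp,
                dimnames = list(NULL, rownames(scores)))
  # per-axis density factors, combined through the cell index matrix
  for (s in seq_len(n_sp)) {
    dens <- rep(1, grid$n_cells)
    for (a in seq_len(grid$n_axes)) {
      fa <- stats::dnorm(grid$centers[[a]], scores[s, a], bandwidths[a])
      dens <- dens * fa[grid$idx[, a]]
    }
    out[, s] <- tpd_trim(dens, trim_alpha)
  }
  out
}

#' Community trait probability density
#'
#' Abundance-weighted mixture of the present species' TPDs, renormalised.
#'
#' @param tpds cells x species matrix from [species_tpd()].
#' @param abund named abundance vector for one sample (names = species
#'   ids); species with positive abundance must have a TPD column.
#' @return density vector over grid cells summing to 1.
#' @export
community_tpd <- function(tpds, abund) {
  present <- names(abund)[abund > 0]
  missing_tpd <- setdiff(present, colnames(tpds))
  if (length(missing_tpd) > 0L) {
    stop("present species without a TPD: ",
         paste(missing_tpd, collapse = ", "))
  }
  w <- abund[present] / sum(abund[present])
  p <- as.numeric(tpds[, present, drop = FALSE] %*% w)
  p / sum(p)
}

#' Functional richness (FRic)
#'
#' The amount of trait space occupied: the community TPD is trimmed to its
#' \code{trim_alpha} highest-density region, and FRic is the number of
#' retained cells times the cell volume.
#'
#' @param p community TPD over grid cells.
#' @param grid the [tpd_grid()].
#' @param trim_alpha mass retained when trimming.
#' @return occupied volume, in trait-space units.
#' @export
tpd_fric <- function(p, grid, trim_alpha = 0.99) {
  q <- tpd_trim(p, trim_alpha)
  sum(q > 0) * grid$cell_volume
}

#' Functional evenness (FEve)
#'
#' Overlap between the (trimmed) community TPD and the uniform density on
#' its occupied support: \code{sum over occupied cells of
#' min(p, 1/N_occupied)}. 1 for a perfectly uniform TPD.
#'
#' @param p trimmed community TPD.
#' @return value in [0, 1].
#' @export
tpd_feve <- function(p) {
  occ <- p > 0
  sum(pmin(p[occ], 1 / sum(occ)))
}

#' Functional divergence (FDiv)
#'
#' Degree to which mass sits far from the centre of the occupied region.
#' With COG the unweighted centroid of occupied cell centres, d the cell
#' distances to COG and dbar their unweighted mean:
#' \code{FDiv = (sum p (d - dbar) + dbar) / (sum p |d - dbar| + dbar)}.
#'
#' @param p trimmed community TPD.
#' @param grid the [tpd_grid()].
#' @return value in [0, 1]; NA with a warning if fewer than two occupied
#'   cells.
#' @export
tpd_fdiv <- function(p, grid) {
  occ <- which(p > 0)
  if (length(occ) < 2L) {
    warning("FDiv undefined with a single occupied cell")
    return(NA_real_)
  }
  coords <- grid_cell_coords(grid, occ)
  cog <- colMeans(coords)
  d <- sqrt(rowSums((coords - rep(cog, each = nrow(coords)))^2))
  dbar <- mean(d)
  delta_d <- sum(p[occ] * (d - dbar))
  delta_ad <- sum(p[occ] * abs(d - dbar))
  (delta_d + dbar) / (delta_ad + dbar)
}

#' Relative functional redundancy
#'
#' The abundance-weighted mean number of species covering each occupied
#' cell, minus one, divided by its upper bound (species richness - 1).
#' 0 when every cell is covered by a single species (or S = 1); 1 when all
#' S species are functionally identical.
#'
#' @param p trimmed community TPD.
#' @param tpds cells x species matrix of trimmed species TPDs.
#' @param abund named abundance vector for the sample.
#' @return relative redundancy in [0, 1].
#' @export
tpd_redundancy <- function(p, tpds, abund) {
  present <- names(abund)[abund > 0]
  s <- length(present)
  if (s == 0L) stop("empty sample")
  if (s == 1L) return(0)
  n_cell <- rowSums(tpds[, present, drop = FALSE] > 0)
  r <- sum(p * n_cell) - 1
  r / (s - 1)
}

#' Overlap-based dissimilarity between two TPDs
#'
#' \code{1 - sum min(a, b)} over cells: 0 for identical densities, 1 for
#' disjoint supports.
#'
#' @param a,b density vectors on the same grid.
#' @return value in [0, 1].
#' @export
tpd_overlap_dissim <- function(a, b) {
  if (length(a) != length(b)) {
    stop("TPDs are defined on different grids")
  }
  1 - sum(pmin(a, b))
}
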