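# Between-sample taxonomic and functional dissimilarity and the
# multivariate location/dispersion tests and ordination built on them.

#' Bray-Curtis dissimilarity between samples
#'
#' BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i) on abundance counts.
#' Backed by [vegan::vegdist()].
#'
#' @param community a [community_matrix()] (or abundance matrix).
#' @return symmetric sample dissimilarity matrix in [0, 1].
#' @export
bray_curtis <- function(community) {
  abund <- if (inherits(community, "community_matrix")) community$abund
    else as.matrix(community)
  if (any(rowSums(abund) == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(abund)[rowSums(abund) == 0], collapse = ", "))
  }
  as.matrix(vegan::vegdist(abund, method = "bray"))
}

#' TPD-overlap functional dissimilarity between samples
#'
#' Pairwise [tpd_overlap_dissim()] over all samples' community TPDs.
#'
#' @param ctpds cells x samples matrix of community TPDs on one grid.
#' @return symmetric sample dissimilarity matrix in [0, 1].
#' @export
functional_dissim <- function(ctpds) {
  n <- ncol(ctpds)
  d <- matrix(0, n, n, dimnames = list(colnames(ctpds), colnames(ctpds)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- tpd_overlap_dissim(ctpds[, i], ctpds[, j])
    }
  }
  d
}

#' PERMANOVA on a sample dissimilarity matrix
#'
#' Distance-based multivariate ANOVA with sequential (Type-I) sums of
#' squares in the order assemblage, area, assemblage:area, and free
#' permutation of sample labels. Backed by [vegan::adonis2()].
#'
#' @param dissim symmetric sample dissimilarity matrix.
#' @param meta per-sample metadata with \code{assemblage} and \code{area}.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return data.frame per term: df, sums of squares, R2, pseudo-F,
#'   permutation p.
#' @export
permanova <- function(dissim, meta, n_perm = 999L, seed = 1L) {
  for (f in c("assemblage", "area")) {
    if (length(unique(meta[[f]])) < 2L) {
      stop("factor ", f, " needs at least 2 levels")
    }
  }
  if (length(unique(paste(meta$assemblage, meta$area))) <
      length(unique(meta$assemblage)) + length(unique(meta$area)) - 1L) {
    stop("assemblage and area are aliased; design is confounded")
  }
  set.seed(as.integer(seed))
  fit <- vegan::adonis2(stats::as.dist(dissim) ~ assemblage * area,
                        data = meta, permutations = n_perm, by = "terms")
  out <- as.data.frame(fit)
  names(out) <- c("df", "ss", "r2", "pseudo_f", "p")
  out$term <- rownames(fit)
  rownames(out) <- NULL
  out[, c("term", "df", "ss", "r2", "pseudo_f", "p")]
}

# geometric (spatial) median by Weiszfeld iterative reweighting, run to
# machine precision; exact for coincident points
spatial_median <- function(points, tol = 1e-14, max_iter = 10000L) {
  if (nrow(points) == 1L || ncol(points) == 0L) {
    return(colMeans(points))
  }
  x <- colMeans(points)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((points - rep(x, each = nrow(points)))^2))
    w <- 1 / pmax(d, 1e-300)
    # when the iterate sits on a data point, nudge via the Weiszfeld
    # modification: cap that point's weight contribution
    w[d < 1e-12] <- 0
    if (all(w == 0)) return(x)
    x_new <- colSums(points * w) / sum(w)
    if (sqrt(sum((x_new - x)^2)) < tol) return(x_new)
    x <- x_new
  }
  x
}

# PCoA embedding keeping real and imaginary axes separately
embed_pcoa <- function(dissim) {
  d <- as.matrix(dissim)
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- a - outer(rowMeans(a), rep(1, n)) - outer(rep(1, n), colMeans(a)) +
    mean(a)
  e <- eigen(g, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values))
  pos <- e$values > tol
  neg <- e$values < -tol
  list(real = e$vectors[, pos, drop = FALSE] %*%
         diag(sqrt(e$values[pos]), sum(pos)),
       imag = e$vectors[, neg, drop = FALSE] %*%
         diag(sqrt(-e$values[neg]), sum(neg)))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Embeds the dissimilarity matrix by PCoA (negative eigenvalues handled by
#' the signed squared-distance convention: imaginary-axis distances
#' subtract), computes each sample's distance to its group's spatial
#' median (Weiszfeld iterative reweighting in the embedded space), and
#' permutation-tests equality of group mean distances with a one-way F on
#' the distances.
#'
#' @param dissim symmetric sample dissimilarity matrix.
#' @param groups grouping factor (e.g. assemblage, or assemblage x area).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with \code{group_means} (mean distance to group median),
#'   \code{distances} per sample, \code{f} and permutation \code{p}.
#' @export
permdisp <- function(dissim, groups, n_perm = 999L, seed = 1L) {
  groups <- as.factor(groups)
  small <- names(table(groups))[table(groups) < 2L]
  if (length(small) > 0L) {
    warning("excluding group(s) of size 1: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    dissim <- dissim[keep, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  emb <- embed_pcoa(dissim)
  dist_to_median <- function(rows) {
    med_r <- spatial_median(emb$real[rows, , drop = FALSE])
    d2 <- rowSums((emb$real[rows, , drop = FALSE] -
                     rep(med_r, each = length(rows)))^2)
    if (ncol(emb$imag) > 0L) {
      med_i <- spatial_median(emb$imag[rows, , drop = FALSE])
      d2 <- d2 - rowSums((emb$imag[rows, , drop = FALSE] -
                            rep(med_i, each = length(rows)))^2)
    }
    sqrt(pmax(d2, 0))
  }
  distances <- numeric(nrow(emb$real))
  names(distances) <- rownames(as.matrix(dissim))
  for (g in levels(groups)) {
    rows <- which(groups == g)
    distances[rows] <- dist_to_median(rows)
  }
  f_stat <- function(z, grp) {
    k <- nlevels(grp)
    n <- length(z)
    gm <- tapply(z, grp, mean)
    ng <- tabulate(grp)
    ssb <- sum(ng * (gm - mean(z))^2)
    ssw <- sum((z - gm[grp])^2)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  if (nlevels(groups) >= 2L) {
    f <- f_stat(distances, groups)
    set.seed(as.integer(seed))
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      if (f_stat(distances[sample.int(length(distances))], groups) >= f) {
        exceed <- exceed + 1L
      }
    }
    p <- (1 + exceed) / (1 + n_perm)
  } else {
    f <- NA_real_
    p <- NA_real_
  }
  list(group_means = tapply(distances, groups, mean),
       distances = distances, f = f, p = p)
}

#' Non-metric multidimensional scaling of samples
#'
#' Kruskal stress-1 NMDS on the dissimilarity matrix, best of
#' \code{n_starts} random starts. Backed by [vegan::metaMDS()] on the
#' supplied distances (no internal transformation).
#'
#' @param dissim symmetric sample dissimilarity matrix.
#' @param k target dimensionality (default 2).
#' @param n_starts random starts.
#' @param max_iter maximum iterations per start.
#' @param seed integer seed.
#' @return list with \code{points} (samples x k), \code{stress} and
#'   \code{converged}.
#' @export
nmds <- function(dissim, k = 2L, n_starts = 20L, max_iter = 500L,
                 seed = 1L) {
  if (k >= nrow(dissim) - 1L) {
    stop("k must be smaller than the number of samples minus 1")
  }
  set.seed(as.integer(seed))
  fit <- vegan::metaMDS(stats::as.dist(dissim), k = k, try = n_starts,
                        trymax = n_starts, maxit = max_iter, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || fit$converged > 0)
}
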