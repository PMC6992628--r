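# Taxonomic diversity, guild diversity, mean pairwise functional distance
# and inventory completeness.

#' Species richness and Gini-Simpson equivalent number
#'
#' @param abund abundance vector for one sample.
#' @return list with \code{richness} (count of species with abundance > 0)
#'   and \code{simpson_equivalent} (1 / sum p^2, the effective number of
#'   equally abundant species).
#' @export
richness_simpson <- function(abund) {
  if (sum(abund) <= 0) stop("sample has zero total abundance")
  p <- abund[abund > 0] / sum(abund)
  list(richness = length(p), simpson_equivalent = 1 / sum(p^2))
}

#' Shannon diversity of trophic guilds
#'
#' Shannon index (nats) over the relative abundances of the five guilds in
#' one sample; bounded by log(5).
#'
#' @param abund named abundance vector for one sample.
#' @param guilds named character vector mapping species id to guild.
#' @return Shannon entropy of the guild abundance distribution.
#' @export
guild_shannon <- function(abund, guilds) {
  present <- names(abund)[abund > 0]
  g <- guilds[present]
  if (anyNA(g)) {
    stop("species without a guild: ",
         paste(present[is.na(g)], collapse = ", "))
  }
  q <- tapply(abund[present], factor(g, levels = GUILD_LEVELS), sum)
  q <- q[!is.na(q) & q > 0] / sum(abund[present])
  -sum(q * log(q))
}

#' Mean pairwise functional distance (MPD)
#'
#' Mean Euclidean distance in the retained trait space over all unordered
#' pairs of co-occurring species. The default is presence-based; the
#' abundance-weighted form uses weights p_i p_j.
#'
#' @param abund named abundance vector for one sample.
#' @param scores species x axes score matrix (rownames = species ids), or a
#'   precomputed distance matrix via \code{dist_matrix}.
#' @param weighted if TRUE, weight pairs by products of relative abundance.
#' @param dist_matrix optional precomputed symmetric species distance
#'   matrix; overrides \code{scores}.
#' @return mean pairwise distance; NA with fewer than two species present.
#' @export
mpd <- function(abund, scores = NULL, weighted = FALSE,
                dist_matrix = NULL) {
  present <- names(abund)[abund > 0]
  if (length(present) < 2L) return(NA_real_)
  if (is.null(dist_matrix)) {
    dist_matrix <- as.matrix(stats::dist(scores[present, , drop = FALSE]))
  } else {
    dist_matrix <- dist_matrix[present, present, drop = FALSE]
  }
  ut <- upper.tri(dist_matrix)
  if (!weighted) return(mean(dist_matrix[ut]))
  p <- abund[present] / sum(abund[present])
  w <- outer(p, p)
  sum(w[ut] * dist_matrix[ut]) / sum(w[ut])
}

#' Inventory completeness from an abundance-based coverage estimator
#'
#' Completeness is 100 x observed richness over estimated richness. The
#' estimator is the abundance-based coverage (ACE-type) estimator: species
#' with abundance at or below \code{rare_cutoff} form the rare group, whose
#' sample coverage is C = 1 - f1/n_rare (f1 = singletons, n_rare = rare
#' individuals); estimated richness is
#' S_abund + S_rare / C + (f1 / C) * gamma^2, with gamma^2 the rare-group
#' squared coefficient of variation estimate, floored at 0. When C = 0
#' (all rare individuals are singletons) the bias-corrected Chao1 estimator
#' is used instead, with a warning.
#'
#' @param abund species abundance vector (zeros allowed and ignored).
#' @param rare_cutoff rare-group abundance cutoff (default 10).
#' @return list with \code{completeness} (percent), \code{s_obs},
#'   \code{s_est}, and the estimator label used.
#' @export
completeness <- function(abund, rare_cutoff = 10L) {
  x <- abund[abund > 0]
  s_obs <- length(x)
  rare <- x[x <= rare_cutoff]
  s_rare <- length(rare)
  s_abund <- s_obs - s_rare
  f1 <- sum(x == 1)
  estimator <- "ACE"
  if (s_rare == 0L) {
    s_est <- s_obs
  } else {
    n_rare <- sum(rare)
    c_ace <- 1 - f1 / n_rare
    if (c_ace <= 0) {
      warning("rare group is all singletons; using bias-corrected Chao1")
      f2 <- sum(x == 2)
      s_est <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
      estimator <- "Chao1-bc"
    } else {
      fk <- tabulate(rare, nbins = rare_cutoff)
      gamma2 <- max(s_rare / c_ace *
                      sum(seq_len(rare_cutoff) *
                            (seq_len(rare_cutoff) - 1) * fk) /
                      (n_rare * (n_rare - 1)) - 1, 0)
      s_est <- s_abund + s_rare / c_ace + f1 / c_ace * gamma2
    }
  }
  list(completeness = 100 * s_obs / s_est, s_obs = s_obs, s_est = s_est,
       estimator = estimator)
}
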