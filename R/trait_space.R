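# Composite trait derivation, standardisation, community-weighted means,
# Gower dissimilarity and the PCoA trait space.

#' Derive the robustness trait from specimen morphometrics
#'
#' Robustness captures body shape independently of body size. For each of
#' the five shape measures (pronotum width, length and depth; elytra width;
#' head width), one least-squares regression on body length is fitted across
#' all specimens pooled. A species' robustness is the mean, over the five
#' regressions, of its specimens' mean residual: a robust species has larger
#' shape measures than expected for its body length. By construction the
#' trait is effectively independent of body length.
#'
#' @param specimens a validated specimen table (see
#'   [validate_specimen_table()]).
#' @return named numeric vector of robustness per species; NA for species
#'   with none of the five measures available.
#' @export
derive_robustness <- function(specimens) {
  validate_specimen_table(specimens)
  measures <- c("pronotum_width", "pronotum_length", "pronotum_depth",
                "elytra_width", "head_width")
  complete_sp <- unique(specimens$species_id[
    stats::complete.cases(specimens[, c("body_length", measures)])])
  if (length(complete_sp) < 3L) {
    stop("robustness regression needs complete measures for >= 3 species")
  }
  species <- unique(specimens$species_id)
  resid_by_measure <- sapply(measures, function(m) {
    ok <- !is.na(specimens[[m]]) & !is.na(specimens$body_length)
    fit <- stats::lm(specimens[[m]][ok] ~ specimens$body_length[ok])
    r <- rep(NA_real_, nrow(specimens))
    r[ok] <- stats::resid(fit)
    tapply(r, factor(specimens$species_id, levels = species), mean,
           na.rm = TRUE)
  })
  out <- rowMeans(resid_by_measure, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Derive elytra ratio, relative eye size, activity period and thermal range
#'
#' @param specimens specimen table; per-specimen ratios (elytra length over
#'   the elytra-base-to-abdomen-apex length; eye surface over head width)
#'   are averaged within species.
#' @param activity data.frame with columns \code{species_id}, \code{area},
#'   \code{month} (integer 1-12) listing when and where each species was
#'   captured as an adult.
#' @param temperature_logs data.frame with columns \code{area},
#'   \code{month}, \code{temperature} (degrees C, monthly mean).
#' @return data.frame with one row per species: \code{ratio_elytra},
#'   \code{eye_size}, \code{months_active} (count of distinct active months
#'   across areas) and \code{temperature_range} (max minus min monthly
#'   temperature over the months-by-areas where the species was active).
#' @export
derive_scalar_traits <- function(specimens, activity, temperature_logs) {
  validate_specimen_table(specimens)
  zero_den <- unique(specimens$species_id[
    (!is.na(specimens$abdomen_from_elytra_base_length) &
       specimens$abdomen_from_elytra_base_length == 0) |
      (!is.na(specimens$head_width) & specimens$head_width == 0)])
  if (length(zero_den) > 0L) {
    stop("zero denominator measure for species: ",
         paste(zero_den, collapse = ", "))
  }
  sp <- factor(specimens$species_id)
  ratio <- tapply(specimens$elytra_length /
                    specimens$abdomen_from_elytra_base_length, sp, mean,
                  na.rm = TRUE)
  eye <- tapply(specimens$eye_surface / specimens$head_width, sp, mean,
                na.rm = TRUE)
  act <- unique(activity[, c("species_id", "area", "month")])
  months_active <- tapply(act$month, factor(act$species_id),
                          function(m) length(unique(m)))
  temps <- merge(act, temperature_logs, by = c("area", "month"))
  temp_range <- tapply(temps$temperature, factor(temps$species_id),
                       function(x) max(x) - min(x))
  ids <- sort(unique(c(levels(sp), names(months_active))))
  data.frame(species_id = ids,
             ratio_elytra = as.numeric(ratio[ids]),
             eye_size = as.numeric(eye[ids]),
             months_active = as.integer(months_active[ids]),
             temperature_range = as.numeric(temp_range[ids]),
             row.names = NULL)
}

#' Standardise quantitative traits
#'
#' Strictly positive quantitative traits are log-transformed and then scaled
#' to mean 0 and unit variance; sign-indefinite or zero-admitting traits
#' (robustness, which is a residual, and temperature_range, which can be 0)
#' are z-scaled without the log. The categorical guild column and missing
#' cells are untouched.
#'
#' @param traits a trait table.
#' @return the trait table with transformed quantitative columns.
#' @export
standardize_traits <- function(traits) {
  z_only <- c("robustness", "temperature_range")
  for (tr in QUANT_TRAITS) {
    x <- traits[[tr]]
    ok <- !is.na(x)
    if (!(tr %in% z_only)) {
      if (any(x[ok] <= 0)) {
        stop("trait ", tr, " has non-positive values; cannot log-transform")
      }
      x[ok] <- log(x[ok])
    }
    s <- sqrt(mean((x[ok] - mean(x[ok]))^2))  # population sd
    if (!is.finite(s) || s == 0) {
      stop("trait ", tr, " has zero variance; cannot scale")
    }
    traits[[tr]] <- (x - mean(x[ok])) / s
  }
  traits
}

#' Community-weighted means
#'
#' For each sample, quantitative trait CWM is the abundance-weighted mean
#' over species with the trait non-missing (weights renormalised to those
#' species); the categorical guild yields five relative-abundance
#' proportions summing to 1.
#'
#' @param community a [community_matrix()].
#' @param traits trait table covering the community's species.
#' @return data.frame, one row per sample: \code{sample_id}, metadata,
#'   \code{cwm_<trait>} columns, and \code{guild_<level>} proportions.
#' @export
cwm <- function(community, traits) {
  abund <- community$abund
  if (any(rowSums(abund) == 0)) {
    stop("sample(s) with zero total abundance: ",
         paste(rownames(abund)[rowSums(abund) == 0], collapse = ", "))
  }
  traits <- traits[match(colnames(abund), traits$species_id), , drop = FALSE]
  out <- community$meta
  for (tr in QUANT_TRAITS) {
    x <- traits[[tr]]
    w <- abund[, !is.na(x), drop = FALSE]
    out[[paste0("cwm_", tr)]] <-
      as.numeric(w %*% x[!is.na(x)]) / rowSums(w)
  }
  g <- as.character(traits$guild)
  wg <- abund[, !is.na(g), drop = FALSE]
  tot <- rowSums(wg)
  for (lev in GUILD_LEVELS) {
    out[[paste0("guild_", lev)]] <-
      rowSums(wg[, g[!is.na(g)] == lev, drop = FALSE]) / tot
  }
  out
}

#' Gower dissimilarity between species
#'
#' Range-normalised mixed-type dissimilarity over the seven traits:
#' quantitative traits contribute |xi - xj| / range, the guild contributes
#' a 0/1 mismatch, and each pair is averaged over its non-missing shared
#' traits. Ranges are computed on the full table supplied. Backed by
#' [cluster::daisy()].
#'
#' @param traits a trait table (typically standardised) for >= 2 species.
#' @return symmetric matrix in [0, 1] with species ids as dimnames.
#' @export
gower_dissim <- function(traits) {
  if (nrow(traits) < 2L) stop("need at least 2 species")
  df <- traits[, QUANT_TRAITS, drop = FALSE]
  df$guild <- factor(traits$guild, levels = GUILD_LEVELS)
  rownames(df) <- traits$species_id
  d <- as.matrix(cluster::daisy(df, metric = "gower",
                                warnBin = FALSE, warnAsym = FALSE,
                                warnConst = FALSE))
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- apply(bad, 1, function(ij) paste(rownames(d)[ij[1]],
                                              colnames(d)[ij[2]],
                                              sep = " / "))
    stop("species pair(s) share no non-missing traits: ",
         paste(pairs, collapse = "; "))
  }
  d
}

#' Principal coordinates trait space
#'
#' Classical metric scaling of the species dissimilarity matrix
#' (double-centred -D^2/2, eigendecomposed; coordinates scaled by the square
#' root of each eigenvalue). Negative eigenvalues are dropped from both the
#' numerator and denominator of the variance fraction.
#'
#' @param dissim symmetric species dissimilarity matrix (e.g. from
#'   [gower_dissim()]).
#' @param n_axes number of axes to retain (default 4).
#' @return object of class \code{trait_space}: list with \code{scores}
#'   (species x axes), \code{eigenvalues} (all), and
#'   \code{variance_fraction} represented by the retained axes.
#' @export
trait_pcoa <- function(dissim, n_axes = 4L) {
  fit <- stats::cmdscale(stats::as.dist(dissim),
                         k = min(as.integer(n_axes), nrow(dissim) - 1L),
                         eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_axes > n_pos) {
    stop("requested ", n_axes, " axes but only ", n_pos,
         " positive eigenvalues are available")
  }
  scores <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(scores) <- paste0("axis", seq_len(n_axes))
  structure(list(scores = scores,
                 eigenvalues = eig,
                 variance_fraction = sum(eig[seq_len(n_axes)]) /
                   sum(eig[eig > 0])),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat("trait_space:", nrow(x$scores), "species on", ncol(x$scores),
      "axes;", sprintf("%.1f%%", 100 * x$variance_fraction),
      "of variation represented\n")
  invisible(x)
}
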