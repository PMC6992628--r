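# Synthetic species pools and communities with plantable assembly signals.
#
# The generator emulates a two-assemblage, three-area trap study: hollow
# emergence traps (HET) sample tree cavities, window traps (WT) intercept
# flying beetles. Sample counts default to the study design (HET 29/27/13
# and WT 22/20/14 across Cabaneros/Quilamas/Azaba). Each assemblage is
# assembled under a known rule (neutral draw, niche filtering around a
# sample-specific trait optimum, or limiting-similarity overdispersion), so
# downstream metrics can be validated against planted truth.

#' Simulation configuration
#'
#' @param n_species_pool size of the core species pool used for assembly.
#' @param guild_probs probabilities over the five [GUILD_LEVELS]; must sum
#'   to 1.
#' @param areas area labels.
#' @param samples_het,samples_wt named integer vectors of samples per area
#'   for the hollow-emergence and window-trap assemblages.
#' @param rule_het,rule_wt assembly rule per assemblage, one of
#'   \code{"neutral"}, \code{"filtering"}, \code{"overdispersion"}.
#' @param sigma_f Gaussian niche-filter width in standardised trait units;
#'   smaller values filter harder.
#' @param delta minimum pairwise trait distance enforced under
#'   overdispersion, in standardised trait units.
#' @param mean_richness mean species richness per sample (Poisson, floored
#'   at 3 and capped at \code{richness_cap}).
#' @param richness_cap upper bound on per-sample richness; keeps the
#'   overdispersion rule seatable at the default spacing.
#' @param abund_meanlog,abund_sdlog log-normal abundance model; draws are
#'   rounded with a floor of 1 individual.
#' @param rare_inject_rate size of the injected rare-species pool (dataset
#'   singletons/doubletons), as a fraction of \code{n_species_pool}.
#' @param missingness_rate probability that a measured quantitative trait
#'   cell (robustness, ratio_elytra, eye_size, temperature_range) is
#'   recorded missing.
#' @param robustness_sd standard deviation (mm) of the planted per-species
#'   robustness offset added to each shape measure's allometric prediction.
#' @param clump_mean_size expected number of species per trait clump
#'   (congener-like groups sharing similar traits); 1 disables clumping.
#' @param clump_within_frac fraction of each trait's variation placed
#'   within clumps (the rest separates clump centres).
#' @param measure_noise_sd log-scale measurement noise on specimen measures.
#' @param rng_seed integer; governs pool, assembly and noise. Per-sample
#'   sub-streams are derived deterministically from it.
#' @return a classed list of settings.
#' @export
sim_config <- function(n_species_pool = 180L,
                       guild_probs = c(predator = 0.15, xylophagous = 0.30,
                                       saproxylophagous = 0.20,
                                       saprophagous = 0.20,
                                       mycetophagous = 0.15),
                       areas = c("Azaba", "Cabaneros", "Quilamas"),
                       samples_het = c(Azaba = 13L, Cabaneros = 29L,
                                       Quilamas = 27L),
                       samples_wt = c(Azaba = 14L, Cabaneros = 22L,
                                      Quilamas = 20L),
                       rule_het = "overdispersion",
                       rule_wt = "filtering",
                       sigma_f = 0.35,
                       delta = 1.8,
                       mean_richness = 28,
                       richness_cap = 32L,
                       abund_meanlog = 1, abund_sdlog = 1.2,
                       rare_inject_rate = 0.15,
                       missingness_rate = 0.03,
                       robustness_sd = 0.8,
                       clump_mean_size = 3,
                       clump_within_frac = 0.3,
                       measure_noise_sd = 0.05,
                       rng_seed = 1L) {
  stopifnot(clump_mean_size >= 1, clump_within_frac >= 0,
            clump_within_frac < 1)
  stopifnot(abs(sum(guild_probs) - 1) < 1e-8, sigma_f > 0, delta >= 0,
            n_species_pool >= 3L)
  rules <- c("neutral", "filtering", "overdispersion")
  stopifnot(rule_het %in% rules, rule_wt %in% rules)
  stopifnot(setequal(names(samples_het), areas),
            setequal(names(samples_wt), areas))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-unit sub-stream seed, kept within 32-bit range
sub_seed <- function(base, i) (as.integer(base) + 7919L * as.integer(i)) %%
  2147483629L

#' Generate a synthetic species pool
#'
#' Draws a core pool plus a small injected-rare pool of species with
#' quantitative traits on realistic scales (body length log-normal in mm,
#' elytra ratio near 1, relative eye size log-normal), guilds multinomial
#' over [GUILD_LEVELS], activity periods of 1-12 months and thermal ranges
#' that widen with the activity period. Specimen-level morphometrics are
#' generated allometrically: each of the five shape measures follows its
#' allometric slope on body length shifted by a planted per-species
#' robustness offset, with log-normal noise, so [derive_robustness()]
#' recovers the planted signal.
#'
#' @param sim a [sim_config()].
#' @return list with \code{traits} (trait table including derived
#'   robustness), \code{specimens}, \code{planted} (data.frame of planted
#'   per-species robustness), and \code{core_species} (ids eligible for
#'   assembly, excluding the injected-rare pool).
#' @export
generate_pool <- function(sim = sim_config()) {
  if (sim$n_species_pool < 3L) stop("need at least 3 species in the pool")
  set.seed(sub_seed(sim$rng_seed, 1L))
  n_rare <- round(sim$rare_inject_rate * sim$n_species_pool)
  n <- sim$n_species_pool + n_rare
  ids <- sprintf("sp%03d", seq_len(n))

  # trait conservatism: species belong to congener-like clumps; each
  # trait's variation splits into a between-clump and a within-clump part
  n_clumps <- max(1L, round(n / sim$clump_mean_size))
  clump <- sample.int(n_clumps, n, replace = TRUE)
  wf <- sim$clump_within_frac
  clumped_lnorm <- function(meanlog, sdlog) {
    centre <- stats::rnorm(n_clumps, meanlog, sdlog * sqrt(1 - wf^2))
    exp(centre[clump] + stats::rnorm(n, 0, sdlog * wf))
  }
  body_length <- clumped_lnorm(1.6, 0.7)
  ratio_elytra <- clumped_lnorm(-0.05, 0.08)
  eye_rel <- clumped_lnorm(-1.2, 0.5)
  months_centre <- 1L + stats::rbinom(n_clumps, 11L, 0.4)
  months <- pmin(12L, pmax(1L, months_centre[clump] +
                             sample(-1:1, n, replace = TRUE)))
  temp_range <- (months - 1) / 11 * 22 * stats::rlnorm(n, 0, 0.2)
  guild <- sample(GUILD_LEVELS, n, replace = TRUE, prob = sim$guild_probs)
  rob_centre <- stats::rnorm(n_clumps, 0, sim$robustness_sd *
                               sqrt(1 - wf^2))
  planted_rob <- rob_centre[clump] +
    stats::rnorm(n, 0, sim$robustness_sd * wf)

  # per-specimen allometric measures
  coefs <- c(pronotum_width = 0.35, pronotum_length = 0.30,
             pronotum_depth = 0.25, elytra_width = 0.40, head_width = 0.25)
  n_spec <- sample(1:10, n, replace = TRUE)
  sp_idx <- rep(seq_len(n), n_spec)
  bl_spec <- body_length[sp_idx] * exp(stats::rnorm(length(sp_idx), 0, 0.05))
  noise <- function() exp(stats::rnorm(length(sp_idx), 0,
                                       sim$measure_noise_sd))
  # shape measures: allometric slope on body length plus the planted
  # robustness offset (shared across the five measures), log-normal noise
  shifted <- pmax(bl_spec + planted_rob[sp_idx], 0.1 * bl_spec)
  specimens <- data.frame(
    species_id = ids[sp_idx],
    body_length = bl_spec,
    pronotum_width = coefs["pronotum_width"] * shifted * noise(),
    pronotum_length = coefs["pronotum_length"] * shifted * noise(),
    pronotum_depth = coefs["pronotum_depth"] * shifted * noise(),
    elytra_width = coefs["elytra_width"] * shifted * noise(),
    head_width = coefs["head_width"] * shifted * noise(),
    elytra_length = 0.6 * bl_spec * ratio_elytra[sp_idx] * noise(),
    abdomen_from_elytra_base_length = 0.6 * bl_spec * noise(),
    eye_surface = eye_rel[sp_idx] * coefs["head_width"] * bl_spec * noise(),
    row.names = NULL)
  validate_specimen_table(specimens)

  robustness <- derive_robustness(specimens)[ids]
  traits <- data.frame(
    species_id = ids,
    body_length = body_length,
    robustness = as.numeric(robustness),
    ratio_elytra = ratio_elytra,
    eye_size = eye_rel,
    months_active = months,
    temperature_range = temp_range,
    guild = guild,
    stringsAsFactors = FALSE)

  if (sim$missingness_rate > 0) {
    for (tr in c("robustness", "ratio_elytra", "eye_size",
                 "temperature_range")) {
      hide <- stats::runif(n) < sim$missingness_rate
      traits[[tr]][hide] <- NA_real_
    }
  }
  validate_trait_table(traits)
  list(traits = traits, specimens = specimens,
       planted = data.frame(species_id = ids, robustness = planted_rob),
       core_species = ids[seq_len(sim$n_species_pool)])
}

# standardised quantitative-trait coordinates used by the assembly rules
# (guild is deliberately excluded so categorical CWM tests stay unconfounded)
assembly_space <- function(traits, core_species) {
  tr <- traits[match(core_species, traits$species_id), , drop = FALSE]
  z <- cbind(log(tr$body_length), tr$robustness, log(tr$ratio_elytra),
             log(tr$eye_size), log(tr$months_active), tr$temperature_range)
  # assembly uses complete coordinates: fill rare missing cells with the mean
  z <- apply(z, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    (col - mean(col)) / stats::sd(col)
  })
  rownames(z) <- core_species
  z
}

draw_species <- function(z, rule, size, sigma_f, delta) {
  n <- nrow(z)
  if (rule == "neutral") {
    return(rownames(z)[sample.int(n, size)])
  }
  if (rule == "filtering") {
    opt <- z[sample.int(n, 1L), ] + stats::rnorm(ncol(z), 0, 0.1)
    d2 <- colSums((t(z) - opt)^2)
    w <- exp(-d2 / (2 * sigma_f^2))
    return(rownames(z)[sample.int(n, size, prob = pmax(w, 1e-12))])
  }
  # overdispersion: sequential acceptance at minimum spacing delta.
  # Each step draws among the still-eligible species (those at least delta
  # from every accepted species) with weight increasing in their distance
  # to the accepted set, the stochastic analogue of farthest-point
  # insertion under limiting similarity.
  d_full <- as.matrix(stats::dist(z))
  accepted <- sample.int(n, 1L)
  while (length(accepted) < size) {
    dmin <- apply(d_full[accepted, , drop = FALSE], 2, min)
    dmin[accepted] <- -1
    eligible <- which(dmin >= delta)
    if (length(eligible) == 0L) break
    w <- dmin[eligible]^4
    nxt <- if (length(eligible) == 1L) eligible else
      sample(eligible, 1L, prob = w)
    accepted <- c(accepted, nxt)
  }
  if (length(accepted) < size) {
    stop("could not seat ", size, " species at minimum spacing delta = ",
         delta, "; use a smaller delta or a larger pool")
  }
  rownames(z)[accepted]
}

#' Assemble synthetic communities from a species pool
#'
#' Builds one sample per trap following the configured design. Neutral
#' samples draw species uniformly; filtering samples weight species by a
#' Gaussian kernel of width \code{sigma_f} around a sample-specific optimum
#' in standardised morphological trait space; overdispersion samples accept
#' species sequentially only when at least \code{delta} away from all
#' accepted species. Abundances are log-normal rounded to integers with a
#' floor of 1; the injected-rare pool contributes dataset-wide singletons
#' and doubletons.
#'
#' @param pool output of [generate_pool()].
#' @param sim the same [sim_config()] used to build the pool.
#' @return list with \code{community} (a [community_matrix()]) and
#'   \code{truth} (per-sample generating rule and its parameters).
#' @export
assemble_communities <- function(pool, sim = sim_config()) {
  z <- assembly_space(pool$traits, pool$core_species)
  design <- rbind(
    data.frame(assemblage = "HET", area = names(sim$samples_het),
               n = as.integer(sim$samples_het), rule = sim$rule_het),
    data.frame(assemblage = "WT", area = names(sim$samples_wt),
               n = as.integer(sim$samples_wt), rule = sim$rule_wt))
  design <- design[rep(seq_len(nrow(design)), design$n), c(1, 2, 4)]
  design$sample_id <- sprintf("%s_%s_%02d", design$assemblage,
                              substr(design$area, 1, 2),
                              stats::ave(seq_len(nrow(design)),
                                         design$assemblage, design$area,
                                         FUN = seq_along))
  rownames(design) <- NULL

  all_ids <- pool$traits$species_id
  abund <- matrix(0, nrow(design), length(all_ids),
                  dimnames = list(design$sample_id, all_ids))
  for (j in seq_len(nrow(design))) {
    set.seed(sub_seed(sim$rng_seed, 100L + j))
    size <- max(3L, stats::rpois(1L, sim$mean_richness))
    size <- min(size, sim$richness_cap, length(pool$core_species))
    sp <- draw_species(z, design$rule[j], size, sim$sigma_f, sim$delta)
    counts <- pmax(1, round(stats::rlnorm(length(sp), sim$abund_meanlog,
                                          sim$abund_sdlog)))
    abund[j, sp] <- counts
  }
  rare_ids <- setdiff(all_ids, pool$core_species)
  if (length(rare_ids) > 0L) {
    set.seed(sub_seed(sim$rng_seed, 7L))
    host <- sample.int(nrow(design), length(rare_ids), replace = TRUE)
    cnt <- sample(1:2, length(rare_ids), replace = TRUE)
    for (k in seq_along(rare_ids)) abund[host[k], rare_ids[k]] <- cnt[k]
  }
  used <- colSums(abund) > 0
  community <- community_matrix(abund[, used, drop = FALSE],
                                design[, c("sample_id", "assemblage",
                                           "area")])
  truth <- design[, c("sample_id", "assemblage", "area", "rule")]
  truth$sigma_f <- ifelse(truth$rule == "filtering", sim$sigma_f, NA_real_)
  truth$delta <- ifelse(truth$rule == "overdispersion", sim$delta, NA_real_)
  list(community = community, truth = truth)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: [generate_pool()] then [assemble_communities()].
#'
#' @param sim a [sim_config()].
#' @return list with \code{traits}, \code{specimens}, \code{community},
#'   \code{truth}, \code{planted}, \code{core_species}.
#' @export
simulate_dataset <- function(sim = sim_config()) {
  pool <- generate_pool(sim)
  asm <- assemble_communities(pool, sim)
  c(pool[c("traits", "specimens", "planted", "core_species")], asm)
}
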