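test_that("robustness is zero for perfectly allometric specimens", {
  bl <- c(5, 10, 20, 8, 15)
  specimens <- data.frame(
    species_id = paste0("s", 1:5),
    body_length = bl,
    pronotum_width = 0.35 * bl, pronotum_length = 0.3 * bl,
    pronotum_depth = 0.25 * bl, elytra_width = 0.4 * bl,
    head_width = 0.25 * bl,
    elytra_length = 0.6 * bl, abdomen_from_elytra_base_length = 0.6 * bl,
    eye_surface = 0.1 * bl)
  rob <- derive_robustness(specimens)
  expect_equal(unname(rob), rep(0, 5), tolerance = 1e-10)
})

test_that("inflated shape measures give positive robustness, others compensate", {
  bl <- c(5, 10, 20)
  specimens <- data.frame(
    species_id = c("fat", "s2", "s3"),
    body_length = bl,
    pronotum_width = 0.35 * bl * c(1.5, 1, 1),
    pronotum_length = 0.3 * bl * c(1.5, 1, 1),
    pronotum_depth = 0.25 * bl * c(1.5, 1, 1),
    elytra_width = 0.4 * bl * c(1.5, 1, 1),
    head_width = 0.25 * bl * c(1.5, 1, 1),
    elytra_length = 0.6 * bl, abdomen_from_elytra_base_length = 0.6 * bl,
    eye_surface = 0.1 * bl)
  rob <- derive_robustness(specimens)
  expect_gt(rob["fat"], 0)
  expect_equal(names(which.max(rob)), "fat")
  expect_lt(min(rob), 0)
  # with one specimen per species the least-squares residuals, and hence
  # the species robustness values, balance to zero
  expect_equal(sum(rob), 0, tolerance = 1e-10)
})

test_that("planted robustness is recovered from simulated specimens", {
  sim <- sim_config(n_species_pool = 50L, rare_inject_rate = 0,
                    missingness_rate = 0, measure_noise_sd = 0.05,
                    rng_seed = 5L)
  pool <- generate_pool(sim)
  rec <- pool$traits$robustness
  planted <- pool$planted$robustness
  expect_gt(cor(rec, planted, method = "spearman"), 0.9)
  # decorrelated from body length
  expect_lt(abs(cor(rec, pool$traits$body_length)), 0.05)
})

test_that("scalar traits follow their defining ratios and ranges", {
  specimens <- data.frame(
    species_id = c("a", "b"),
    body_length = c(10, 8),
    pronotum_width = c(3, 2), pronotum_length = c(3, 2),
    pronotum_depth = c(2, 1.5), elytra_width = c(4, 3),
    head_width = c(2, 2),
    elytra_length = c(6, 5), abdomen_from_elytra_base_length = c(6, 4),
    eye_surface = c(0.5, 0.4))
  activity <- data.frame(
    species_id = c("a", "a", "a", "b"),
    area = c("X", "X", "Y", "X"),
    month = c(4L, 5L, 4L, 6L))
  logs <- data.frame(area = c("X", "X", "X", "Y"),
                     month = c(4L, 5L, 6L, 4L),
                     temperature = c(12, 18, 25, 25))
  tr <- derive_scalar_traits(specimens, activity, logs)
  expect_equal(tr$ratio_elytra[tr$species_id == "a"], 1.0)
  expect_equal(tr$eye_size[tr$species_id == "a"], 0.25)
  expect_equal(tr$months_active[tr$species_id == "a"], 2L)
  # a active in months x areas with temps {12, 18, 25}: range 13
  expect_equal(tr$temperature_range[tr$species_id == "a"], 13)
  # b active in a single month in a single area: degenerate range 0
  expect_equal(tr$temperature_range[tr$species_id == "b"], 0)
  specimens$head_width[2] <- 0
  expect_error(derive_scalar_traits(specimens, activity, logs), "b")
})

test_that("standardisation logs positive traits, z-scales sign-indefinite ones", {
  tr <- random_traits(3)
  tr$body_length <- c(1, 10, 100)
  std <- standardize_traits(tr)
  expect_equal(std$body_length, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # robustness keeps its negatives: z-scale only
  tr2 <- random_traits(10, seed = 2)
  std2 <- standardize_traits(tr2)
  expect_equal(mean(std2$robustness), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(std2$robustness^2)), 1, tolerance = 1e-12)
  expect_equal(cor(std2$robustness, tr2$robustness), 1)
  # the z-scale step is idempotent: feeding back an already-standardised
  # robustness column leaves it unchanged
  tr2b <- tr2
  tr2b$robustness <- std2$robustness
  expect_equal(standardize_traits(tr2b)$robustness, std2$robustness,
               tolerance = 1e-12)
  tr3 <- random_traits(5)
  tr3$eye_size <- rep(2, 5)
  expect_error(standardize_traits(tr3), "zero variance")
})

test_that("community-weighted means follow the weighted-average contract", {
  comm <- community_matrix(
    matrix(c(5, 0, 0), 1, 3, dimnames = list("s1", c("spA", "spB", "spC"))),
    data.frame(sample_id = "s1", assemblage = "HET", area = "Azaba"))
  tr <- tiny_traits()
  one <- cwm(comm, tr)
  expect_equal(one$cwm_body_length, 5)
  expect_equal(one$guild_predator, 1)
  # two species, equal abundance, trait 0 and 1
  tr2 <- tiny_traits()
  tr2$robustness <- c(0, 1, NA)
  ab <- matrix(c(2, 2, 1), 1, 3,
               dimnames = list("s1", c("spA", "spB", "spC")))
  comm2 <- community_matrix(ab, data.frame(sample_id = "s1",
                                           assemblage = "HET",
                                           area = "Azaba"))
  res2 <- cwm(comm2, tr2)
  expect_equal(res2$cwm_robustness, 0.5)  # spC missing: renormalised
  # guild proportions (3, 1) -> (0.75, 0.25)
  ab3 <- matrix(c(3, 1, 0), 1, 3,
                dimnames = list("s1", c("spA", "spB", "spC")))
  comm3 <- community_matrix(ab3, comm2$meta)
  res3 <- cwm(comm3, tr2)
  expect_equal(res3$guild_predator, 0.75)
  expect_equal(res3$guild_saprophagous, 0.25)
  guild_cols <- paste0("guild_", GUILD_LEVELS)
  expect_equal(sum(res3[, guild_cols]), 1)
  # zero-abundance sample errors
  ab0 <- matrix(c(0, 0, 0), 1, 3,
                dimnames = list("s1", c("spA", "spB", "spC")))
  expect_error(cwm(community_matrix(ab0, comm2$meta), tr2), "zero total")
})

test_that("Gower dissimilarity matches the brute-force oracle", {
  # hand case: one quantitative trait at range extremes + different guilds
  tr <- tiny_traits()[1:2, ]
  tr[, QUANT_TRAITS] <- NA
  tr$body_length <- c(1, 10)
  tr$guild <- c("predator", "xylophagous")
  # all-NA companion columns make daisy warn about empty ranges; the
  # dissimilarity itself is well-defined from the two shared traits
  d <- suppressWarnings(gower_dissim(tr))
  expect_equal(d[1, 2], 1.0)
  # identical rows
  tr2 <- tiny_traits()[c(1, 1), ]
  tr2$species_id <- c("x", "y")
  expect_equal(gower_dissim(tr2)["x", "y"], 0)
  # property: random 6-species tables with missing cells, to 1e-12
  for (seed in 1:10) {
    tr3 <- random_traits(6, missing_rate = 0.2, seed = seed)
    oracle <- gower_oracle(tr3)
    if (anyNA(oracle)) next
    expect_equal(gower_dissim(tr3), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # a pair sharing no traits errors
  tr4 <- tiny_traits()[1:2, ]
  tr4[1, c("robustness", "ratio_elytra", "eye_size", "guild",
           "months_active")] <- NA
  tr4[2, c("body_length", "temperature_range")] <- NA
  suppressWarnings(expect_error(gower_dissim(tr4), "no non-missing"))
})

test_that("PCoA recovers planted configurations and reports variance honestly", {
  # collinear points: a single positive axis carries all the variance
  x <- matrix(c(0, 1, 2), dimnames = list(c("a", "b", "c"), NULL))
  d <- as.matrix(dist(x))
  ts1 <- trait_pcoa(d, n_axes = 1)
  expect_equal(ts1$variance_fraction, 1.0)
  expect_error(trait_pcoa(d, n_axes = 2), "positive eigenvalues")
  # planted 2-D configuration recovered up to rotation/reflection
  set.seed(4)
  pts <- matrix(rnorm(24), 12, 2,
                dimnames = list(sprintf("p%02d", 1:12), NULL))
  ts2 <- trait_pcoa(as.matrix(dist(pts)), n_axes = 2)
  proc <- vegan::procrustes(pts, ts2$scores, symmetric = FALSE)
  expect_lt(sum(proc$residuals^2), 1e-8)
  # positive eigenvalues sum to the total inertia of the centred matrix
  d2 <- as.matrix(dist(pts))
  a <- -0.5 * d2^2
  n <- nrow(a)
  g <- a - outer(rowMeans(a), rep(1, n)) - outer(rep(1, n), colMeans(a)) +
    mean(a)
  eig <- trait_pcoa(d2, 2)$eigenvalues
  expect_equal(sum(eig[eig > 0]), sum(diag(g)), tolerance = 1e-8)
})
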