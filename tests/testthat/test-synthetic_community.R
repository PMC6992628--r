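# Small configs keep the generator tests fast; effect-size recovery at the
# documented defaults is exercised in test-acceptance.R.

small_sim <- function(...) {
  sim_config(n_species_pool = 60L,
             samples_het = c(Azaba = 3L, Cabaneros = 3L, Quilamas = 3L),
             samples_wt = c(Azaba = 3L, Cabaneros = 3L, Quilamas = 3L),
             mean_richness = 10, ...)
}

test_that("identical seeds reproduce identical outputs bit-for-bit", {
  d1 <- simulate_dataset(small_sim(rng_seed = 42L))
  d2 <- simulate_dataset(small_sim(rng_seed = 42L))
  expect_identical(d1$traits, d2$traits)
  expect_identical(d1$community$abund, d2$community$abund)
  d3 <- simulate_dataset(small_sim(rng_seed = 43L))
  expect_false(identical(d1$community$abund, d3$community$abund))
})

test_that("generated tables pass input validation and referential checks", {
  d <- simulate_dataset(small_sim(rng_seed = 7L))
  expect_silent(validate_trait_table(d$traits))
  expect_silent(validate_specimen_table(d$specimens))
  expect_true(all(colnames(d$community$abund) %in% d$traits$species_id))
  expect_true(all(d$community$abund == round(d$community$abund)))
  expect_true(all(d$community$abund >= 0))
  # one truth label per sample
  expect_setequal(d$truth$sample_id, rownames(d$community$abund))
  expect_false(anyNA(d$truth$rule))
})

test_that("guild proportions match the configured probabilities at large n", {
  probs <- c(predator = 0.1, xylophagous = 0.4, saproxylophagous = 0.2,
             saprophagous = 0.2, mycetophagous = 0.1)
  pool <- generate_pool(sim_config(n_species_pool = 5000L,
                                   guild_probs = probs,
                                   rare_inject_rate = 0, rng_seed = 1L))
  obs <- table(factor(pool$traits$guild, GUILD_LEVELS)) /
    nrow(pool$traits)
  # 4 binomial sds at n = 5000
  tol <- 4 * sqrt(probs * (1 - probs) / 5000)
  expect_true(all(abs(as.numeric(obs) - probs) < tol))
})

test_that("missingness rate 0 yields a complete trait table", {
  pool <- generate_pool(small_sim(missingness_rate = 0, rng_seed = 3L))
  expect_false(anyNA(pool$traits[, ALL_TRAITS]))
})

test_that("overdispersion enforces the minimum trait spacing by construction", {
  sim <- small_sim(rule_het = "overdispersion", rule_wt = "overdispersion",
                   delta = 0.8, rng_seed = 9L)
  d <- simulate_dataset(sim)
  pool <- generate_pool(sim)
  z <- traitvolume:::assembly_space(pool$traits, pool$core_species)
  core <- intersect(colnames(d$community$abund), pool$core_species)
  for (j in seq_len(nrow(d$community$abund))) {
    sp <- intersect(names(which(d$community$abund[j, ] > 0)), core)
    if (length(sp) >= 2) {
      expect_gte(min(dist(z[sp, ])), sim$delta)
    }
  }
})

test_that("filtering narrows within-sample trait variance; a wide kernel is neutral", {
  sim_f <- sim_config(n_species_pool = 150L,
                      samples_het = c(Azaba = 34L, Cabaneros = 33L,
                                      Quilamas = 33L),
                      samples_wt = c(Azaba = 34L, Cabaneros = 33L,
                                     Quilamas = 33L),
                      rule_het = "filtering", rule_wt = "filtering",
                      sigma_f = 0.35, mean_richness = 8,
                      rare_inject_rate = 0, rng_seed = 21L)
  d <- simulate_dataset(sim_f)
  pool <- generate_pool(sim_f)
  z <- traitvolume:::assembly_space(pool$traits, pool$core_species)
  pool_var <- mean(apply(z, 2, var))
  within_var <- apply(d$community$abund, 1, function(w) {
    sp <- intersect(names(which(w > 0)), rownames(z))
    mean(apply(z[sp, , drop = FALSE], 2, var))
  })
  expect_gt(mean(within_var < pool_var), 0.95)
  # sigma_f -> infinity: variance ratio around 1
  sim_n <- sim_config(n_species_pool = 150L,
                      samples_het = c(Azaba = 34L, Cabaneros = 33L,
                                      Quilamas = 33L),
                      samples_wt = c(Azaba = 34L, Cabaneros = 33L,
                                     Quilamas = 33L),
                      rule_het = "filtering", rule_wt = "filtering",
                      sigma_f = 1e6, mean_richness = 8,
                      rare_inject_rate = 0, rng_seed = 21L)
  dn <- simulate_dataset(sim_n)
  wide_var <- apply(dn$community$abund, 1, function(w) {
    sp <- intersect(names(which(w > 0)), rownames(z))
    mean(apply(z[sp, , drop = FALSE], 2, var))
  })
  expect_lt(abs(mean(wide_var) / pool_var - 1), 0.1)
})

test_that("unseatable spacing and degenerate pools raise errors", {
  expect_error(sim_config(n_species_pool = 2L))
  sim <- small_sim(rule_het = "overdispersion", delta = 50, rng_seed = 2L)
  pool <- generate_pool(sim)
  expect_error(assemble_communities(pool, sim), "smaller delta")
})
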