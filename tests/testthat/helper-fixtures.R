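# Fixtures and independent brute-force oracles shared across test files.

tiny_traits <- function() {
  data.frame(
    species_id = c("spA", "spB", "spC"),
    body_length = c(5, 10, 20),
    robustness = c(-0.2, 0, 0.3),
    ratio_elytra = c(0.8, 1.0, 1.1),
    eye_size = c(0.1, 0.3, 0.2),
    months_active = c(3L, 6L, 9L),
    temperature_range = c(5, 10, 15),
    guild = c("predator", "saprophagous", "xylophagous"),
    stringsAsFactors = FALSE)
}

tiny_community <- function(abund = NULL) {
  if (is.null(abund)) {
    abund <- matrix(c(3, 1, 0,
                      0, 2, 5,
                      1, 1, 1,
                      4, 0, 2),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(paste0("s", 1:4),
                                    c("spA", "spB", "spC")))
  }
  meta <- data.frame(sample_id = rownames(abund),
                     assemblage = c("HET", "HET", "WT", "WT"),
                     area = c("Azaba", "Cabaneros", "Azaba", "Cabaneros"))
  community_matrix(abund, meta)
}

# random full trait table for property tests
random_traits <- function(n, missing_rate = 0, seed = 1) {
  set.seed(seed)
  tr <- data.frame(
    species_id = sprintf("r%02d", seq_len(n)),
    body_length = rlnorm(n, 1.5, 0.5),
    robustness = rnorm(n, 0, 0.2),
    ratio_elytra = rlnorm(n, 0, 0.1),
    eye_size = rlnorm(n, -1, 0.4),
    months_active = sample(1:12, n, replace = TRUE),
    temperature_range = runif(n, 0, 25),
    guild = sample(GUILD_LEVELS, n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (missing_rate > 0) {
    for (cl in QUANT_TRAITS) {
      hide <- runif(n) < missing_rate
      tr[[cl]][hide] <- NA
    }
  }
  tr
}

# exhaustive per-pair Gower oracle: range-normalised quantitative traits,
# 0/1 categorical mismatch, averaged over non-missing shared traits
gower_oracle <- function(traits) {
  n <- nrow(traits)
  rngs <- sapply(QUANT_TRAITS, function(cl) {
    diff(range(traits[[cl]], na.rm = TRUE))
  })
  d <- matrix(0, n, n, dimnames = list(traits$species_id,
                                       traits$species_id))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0
      den <- 0
      for (cl in QUANT_TRAITS) {
        xi <- traits[[cl]][i]
        xj <- traits[[cl]][j]
        if (!is.na(xi) && !is.na(xj) && rngs[cl] > 0) {
          num <- num + abs(xi - xj) / rngs[cl]
          den <- den + 1
        }
      }
      gi <- traits$guild[i]
      gj <- traits$guild[j]
      if (!is.na(gi) && !is.na(gj)) {
        num <- num + (gi != gj)
        den <- den + 1
      }
      d[i, j] <- if (den == 0) NA_real_ else num / den
    }
  }
  d
}

# all-pairs MPD oracle
mpd_oracle <- function(abund, scores) {
  present <- names(abund)[abund > 0]
  if (length(present) < 2) return(NA_real_)
  tot <- 0
  k <- 0
  for (i in seq_along(present)[-1]) {
    for (j in seq_len(i - 1)) {
      tot <- tot + sqrt(sum((scores[present[i], ] -
                               scores[present[j], ])^2))
      k <- k + 1
    }
  }
  tot / k
}

# double-loop Bray-Curtis oracle
bray_oracle <- function(abund) {
  n <- nrow(abund)
  d <- matrix(0, n, n, dimnames = list(rownames(abund), rownames(abund)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(abund[i, ] - abund[j, ])) /
        sum(abund[i, ] + abund[j, ])
    }
  }
  d
}

# step-up BH oracle: min over j >= i of p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(rank(p, ties.method = "first")[ord] >= i)
    adj[ord[i]] <- min(1, min(p[ord][js] * m / js))
  }
  adj
}

# spatial median by direct optimisation (Weiszfeld-free oracle)
spatial_median_oracle <- function(points) {
  obj <- function(v) sum(sqrt(rowSums((points -
                                         rep(v, each = nrow(points)))^2)))
  optim(colMeans(points), obj, method = "Nelder-Mead",
        control = list(reltol = 1e-14, maxit = 5000))$par
}

# write the tiny dataset to CSVs in a temp dir, return paths
write_tiny_inputs <- function(dir = tempfile("inputs")) {
  dir.create(dir)
  traits <- tiny_traits()
  comm <- tiny_community()
  long <- as.data.frame(as.table(comm$abund))
  names(long) <- c("sample_id", "species_id", "abundance")
  long <- long[long$abundance > 0, ]
  specimens <- data.frame(
    species_id = rep(c("spA", "spB", "spC"), each = 2),
    body_length = c(5, 5.2, 10, 9.8, 20, 20.4),
    pronotum_width = c(1.8, 1.9, 3.5, 3.4, 7.1, 7.2),
    pronotum_length = c(1.5, 1.6, 3.0, 2.9, 6.0, 6.1),
    pronotum_depth = c(1.2, 1.3, 2.5, 2.4, 5.0, 5.1),
    elytra_width = c(2.0, 2.1, 4.0, 3.9, 8.0, 8.1),
    elytra_length = c(3.0, 3.1, 6.0, 5.9, 12.0, 12.1),
    head_width = c(1.2, 1.3, 2.5, 2.4, 5.0, 5.1),
    abdomen_from_elytra_base_length = c(3.5, 3.6, 6.5, 6.4, 13.0, 13.1),
    eye_surface = c(0.12, 0.13, 0.75, 0.74, 1.0, 1.1))
  paths <- list(traits = file.path(dir, "traits.csv"),
                specimens = file.path(dir, "specimens.csv"),
                community = file.path(dir, "community.csv"),
                meta = file.path(dir, "meta.csv"))
  write.csv(traits, paths$traits, row.names = FALSE)
  write.csv(specimens, paths$specimens, row.names = FALSE)
  write.csv(long, paths$community, row.names = FALSE)
  write.csv(comm$meta, paths$meta, row.names = FALSE)
  paths
}
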