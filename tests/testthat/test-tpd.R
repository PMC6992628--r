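# 1-D and 2-D grids make the TPD metrics checkable against closed forms.

grid_1d <- function(scores, h, cells, names = NULL) {
  if (is.null(names)) names <- paste0("s", seq_along(scores))
  m <- matrix(scores, dimnames = list(names, NULL))
  tpd_grid(m, cells_per_axis = cells, bandwidths = h)
}

test_that("grid bounds, cell counts and the cap behave as specified", {
  g <- grid_1d(c(0, 1), h = 0.5, cells = 10)
  expect_equal(g$lower, -1.5, ignore_attr = TRUE)
  expect_equal(g$upper, 2.5, ignore_attr = TRUE)
  expect_equal(g$widths, 0.4, ignore_attr = TRUE)
  g4 <- tpd_grid(matrix(rnorm(40), 10, 4), cells_per_axis = 15)
  expect_equal(g4$n_cells, 15L^4L)
  expect_error(tpd_grid(matrix(rnorm(40), 10, 4), cells_per_axis = 15,
                        cell_cap = 1000), "cap")
  expect_error(grid_1d(c(0, 1), h = -1, cells = 10), "positive")
})

test_that("species TPDs are normalised, trimmed to the Gaussian HDR, and equal for equal scores", {
  # wide grid (bounds at 3 x h_grid = 9 sigma) so edge truncation is
  # negligible against the Gaussian quantile oracle
  g <- grid_1d(c(0, 0), h = 3, cells = 301)
  tpds <- species_tpd(matrix(c(0, 0), dimnames = list(c("a", "b"), NULL)),
                      g, trim_alpha = 0.99, bandwidths = 1)
  expect_equal(colSums(tpds), c(a = 1, b = 1), tolerance = 1e-9)
  expect_equal(tpds[, "a"], tpds[, "b"])
  # trimmed support of a unit Gaussian at alpha 0.99: 2 * 2.5758 sigma
  support <- sum(tpds[, "a"] > 0) * g$widths[1]
  expect_lt(abs(support - 2 * qnorm(0.995)), g$widths[1] + 1e-9)
})

test_that("community TPDs are abundance-weighted mixtures", {
  g <- grid_1d(c(0, 40), h = 1, cells = 400, names = c("a", "b"))
  tpds <- species_tpd(matrix(c(0, 40), dimnames = list(c("a", "b"), NULL)),
                      g)
  one <- community_tpd(tpds, c(a = 7, b = 0))
  expect_equal(one, unname(tpds[, "a"]))
  # mixture of identical species equals either component
  tpds2 <- species_tpd(matrix(c(0, 0), dimnames = list(c("a", "b"), NULL)),
                       g)
  mix <- community_tpd(tpds2, c(a = 3, b = 9))
  expect_equal(mix, unname(tpds2[, "a"]), tolerance = 1e-12)
  # disjoint supports split mass 0.9 / 0.1
  mix2 <- community_tpd(tpds, c(a = 9, b = 1))
  on_a <- tpds[, "a"] > 0
  expect_equal(sum(mix2[on_a]), 0.9, tolerance = 1e-9)
  expect_equal(sum(mix2), 1, tolerance = 1e-12)
  expect_error(community_tpd(tpds, c(a = 1, zz = 2)), "zz")
})

test_that("FRic matches the Gaussian highest-density-region closed form", {
  g <- grid_1d(0, h = 3, cells = 301, names = "a")
  # untrimmed species density: tpd_fric applies the single 0.99 trim
  tpds <- species_tpd(matrix(0, dimnames = list("a", NULL)), g,
                      trim_alpha = 1, bandwidths = 1)
  fr <- tpd_fric(tpds[, "a"], g)
  expect_lt(abs(fr - 2 * qnorm(0.995)), g$widths[1] + 1e-9)
  # coincident species add nothing
  g2 <- grid_1d(c(0, 0), h = 1, cells = 301)
  tp2 <- species_tpd(matrix(c(0, 0), dimnames = list(c("a", "b"), NULL)),
                     g2)
  expect_equal(tpd_fric(community_tpd(tp2, c(a = 1, b = 1)), g2),
               tpd_fric(tp2[, "a"], g2))
  # two Gaussians 20 sigma apart roughly double the volume
  g3 <- grid_1d(c(0, 20), h = 1, cells = 600, names = c("a", "b"))
  tp3 <- species_tpd(matrix(c(0, 20), dimnames = list(c("a", "b"), NULL)),
                     g3)
  fr1 <- tpd_fric(tp3[, "a"], g3)
  fr2 <- tpd_fric(community_tpd(tp3, c(a = 1, b = 1)), g3)
  expect_lt(abs(fr2 - 2 * fr1), 3 * g3$widths[1])
})

test_that("FEve is 1 for uniform densities and near 0 for spikes", {
  p <- rep(1 / 100, 100)
  expect_equal(tpd_feve(p), 1.0)
  spike <- c(1 - 99 * 1e-6, rep(1e-6, 99))
  expect_equal(tpd_feve(spike), 1 / 100 + 99 * 1e-6, tolerance = 1e-9)
  # invariant under relabelling of cells
  set.seed(1)
  q <- runif(50)
  q <- q / sum(q)
  expect_equal(tpd_feve(q), tpd_feve(sample(q)))
})

test_that("FDiv matches the direct cell-sum oracle on a 1-D grid", {
  g <- grid_1d(c(0, 4), h = 0.5, cells = 5)
  centers <- g$centers[[1]]
  # uniform density: numerator reduces to dbar
  p <- rep(0.2, 5)
  cog <- mean(centers)
  d <- abs(centers - cog)
  dbar <- mean(d)
  expected <- dbar / (sum(p * abs(d - dbar)) + dbar)
  expect_equal(tpd_fdiv(p, g), expected, tolerance = 1e-12)
  # all mass at the maximal-distance cells: FDiv -> 1
  p_far <- c(0.5, 1e-9, 1e-9, 1e-9, 0.5)
  p_far <- p_far / sum(p_far)
  expect_gt(tpd_fdiv(p_far, g), 0.99)
  # nearly all mass closest to the centroid: low FDiv
  p_near <- c(1e-9, 1e-9, 1, 1e-9, 1e-9)
  p_near <- p_near / sum(p_near)
  expect_lt(tpd_fdiv(p_near, g), 0.5)
  expect_warning(res <- tpd_fdiv(c(1, 0, 0, 0, 0), g), "single occupied")
  expect_true(is.na(res))
})

test_that("relative redundancy spans 0 (disjoint) to 1 (identical species)", {
  g <- grid_1d(c(0, 40), h = 1, cells = 400, names = c("a", "b"))
  tp <- species_tpd(matrix(c(0, 40), dimnames = list(c("a", "b"), NULL)),
                    g)
  p <- tpd_trim(community_tpd(tp, c(a = 1, b = 1)), 0.99)
  expect_equal(tpd_redundancy(p, tp, c(a = 1, b = 1)), 0, tolerance = 1e-9)
  expect_equal(tpd_redundancy(p, tp, c(a = 5, b = 0)), 0)
  # S identical species attain the upper bound
  sc <- matrix(rep(0, 4), dimnames = list(letters[1:4], NULL))
  g2 <- grid_1d(rep(0, 4), h = 1, cells = 101)
  tp2 <- species_tpd(sc, g2)
  w <- c(a = 4, b = 3, c = 2, d = 1)
  p2 <- tpd_trim(community_tpd(tp2, w), 0.99)
  expect_equal(tpd_redundancy(p2, tp2, w), 1.0, tolerance = 1e-9)
})

test_that("overlap dissimilarity is a bounded symmetric overlap complement", {
  g <- grid_1d(c(0, 40), h = 1, cells = 400, names = c("a", "b"))
  tp <- species_tpd(matrix(c(0, 40), dimnames = list(c("a", "b"), NULL)),
                    g)
  expect_equal(tpd_overlap_dissim(tp[, "a"], tp[, "a"]), 0)
  expect_equal(tpd_overlap_dissim(tp[, "a"], tp[, "b"]), 1)
  # half mixture against a pure component, disjoint supports: 0.5
  mix <- community_tpd(tp, c(a = 1, b = 1))
  expect_equal(tpd_overlap_dissim(mix, tp[, "a"]), 0.5, tolerance = 1e-9)
  expect_equal(tpd_overlap_dissim(mix, tp[, "b"]),
               tpd_overlap_dissim(tp[, "b"], mix))
  expect_error(tpd_overlap_dissim(tp[, "a"], rep(0.1, 10)),
               "different grids")
})

test_that("FRic is stable under grid refinement and monotone under disjoint addition", {
  sc <- matrix(c(0, 1.5, 3, -2), dimnames = list(letters[1:4], NULL))
  w <- c(a = 3, b = 2, c = 1, d = 2)
  g_coarse <- tpd_grid(sc, cells_per_axis = 40, bandwidths = 0.6)
  g_fine <- tpd_grid(sc, cells_per_axis = 80, bandwidths = 0.6)
  f_coarse <- tpd_fric(community_tpd(species_tpd(sc, g_coarse), w),
                       g_coarse)
  f_fine <- tpd_fric(community_tpd(species_tpd(sc, g_fine), w), g_fine)
  expect_lt(abs(f_fine - f_coarse) / f_coarse, 0.1)
  # 2-D refinement
  sc2 <- matrix(c(0, 1, 0.5, 0, 0.8, 1.2), 3, 2,
                dimnames = list(letters[1:3], NULL))
  w2 <- c(a = 1, b = 1, c = 2)
  for (cells in c(20, 40)) {
    g2 <- tpd_grid(sc2, cells_per_axis = cells, bandwidths = c(0.4, 0.4))
    assign(paste0("f", cells),
           tpd_fric(community_tpd(species_tpd(sc2, g2), w2), g2))
  }
  expect_lt(abs(f40 - f20) / f20, 0.1)
  # adding a disjoint-support species cannot shrink FRic
  g <- grid_1d(c(0, 30), h = 1, cells = 500, names = c("a", "b"))
  tp <- species_tpd(matrix(c(0, 30), dimnames = list(c("a", "b"), NULL)),
                    g)
  expect_gte(tpd_fric(community_tpd(tp, c(a = 1, b = 1)), g),
             tpd_fric(tp[, "a"], g))
})
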