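quadrant_layout <- function(identities) {
  tibble::tibble(x = c(1, 9, 1, 9), y = c(1, 1, 9, 9),
                 identity = identities)
}

test_that("grid variance handles pure and hand-computed cases", {
  lay <- gen_tissue_layout(400, p_bl6 = 1, seed_size = 1, rng_seed = 1)
  expect_equal(grid_variance(lay, 4)$variance, 0)

  gv <- grid_variance(quadrant_layout(c("BL6", "BL6", "JF1", "JF1")), 2)
  expect_equal(sort(gv$tiles$frac_bl6), c(0, 0, 1, 1))
  expect_equal(gv$variance, 1 / 3)  # sample variance of (1, 1, 0, 0)
})

test_that("grid variance is invariant to global allele relabeling", {
  lay <- gen_tissue_layout(500, 0.4, seed_size = 3, rng_seed = 2)
  swapped <- dplyr::mutate(lay, identity = ifelse(identity == "BL6",
                                                  "JF1", "BL6"))
  expect_equal(grid_variance(lay, 6)$variance,
               grid_variance(swapped, 6)$variance)
})

test_that("degenerate grids are rejected with guidance", {
  one_tile <- tibble::tibble(x = c(1, 2), y = c(1, 2),
                             identity = c("BL6", "JF1"))
  expect_error(grid_variance(one_tile, 1), "fewer than two rectangles")
})

test_that("permuting an all-BL6 layout leaves every null variance at zero", {
  lay <- gen_tissue_layout(200, p_bl6 = 1, seed_size = 1, rng_seed = 3)
  pn <- permutation_null(lay, 4, n_perm = 50, rng_seed = 4)
  expect_true(all(pn$variance == 0))
})

test_that("permutation null mean matches the finite-population binomial expectation", {
  # equal occupancy by construction: m points per rectangle of a g x g grid
  g <- 4; m <- 50; n <- g * g * m
  pos <- expand.grid(gx = seq_len(g), gy = seq_len(g))
  pos <- pos[rep(seq_len(nrow(pos)), each = m), ]
  lay <- withr::with_seed(5, tibble::tibble(
    x = (pos$gx - 1) * 10 + runif(n, 1, 9),
    y = (pos$gy - 1) * 10 + runif(n, 1, 9),
    identity = sample(rep(c("BL6", "JF1"), n / 2))))
  pn <- permutation_null(lay, g, n_perm = 3000, rng_seed = 6)
  k <- g * g
  # E[sample variance] for multivariate hypergeometric sampling with the
  # pooled fraction fixed: f(1-f)/m * (N-m)/(N-1) * K/(K-1)
  analytic <- 0.25 / m * (n - m) / (n - 1) * k / (k - 1)
  expect_lt(abs(attr(pn, "mean") / analytic - 1), 0.05)
})

test_that("seeded-cluster null at seed 1 matches the permutation null", {
  lay <- gen_tissue_layout(1000, 0.5, seed_size = 1, rng_seed = 7)
  pn <- permutation_null(lay, 8, n_perm = 500, rng_seed = 8)
  sn <- seeded_cluster_null(lay, 8, seed_sizes = 1, n_sim = 500,
                            rng_seed = 9)
  ks <- suppressWarnings(ks.test(pn$variance, sn$variance))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("mean simulated variance grows with seed size and preserves the ratio", {
  lay <- gen_tissue_layout(1000, 0.5, seed_size = 1, rng_seed = 10)
  sn <- seeded_cluster_null(lay, 8, seed_sizes = c(1, 2, 4, 8), n_sim = 100,
                            rng_seed = 11)
  means <- tapply(sn$variance, sn$seed_size, mean)
  expect_true(all(diff(means) > 0))
})

test_that("exact ratio preservation holds in every null simulation", {
  lay <- gen_tissue_layout(500, 0.5, seed_size = 2, rng_seed = 12)
  n_bl6 <- sum(lay$identity == "BL6")
  sims <- withr::with_seed(13, replicate(20, {
    sum(allelefish:::reseed_identities(lay$x, lay$y, 2, n_bl6) == "BL6")
  }))
  expect_true(all(sims == n_bl6))
})

test_that("seed matching picks the nearest null mean with small-seed ties", {
  observed <- tibble::tibble(grid = c(4L, 8L), variance = c(0.021, 0.021))
  nulls <- tidyr::expand_grid(grid = c(4L, 8L), seed_size = c(1, 2, 4),
                              sim = 1:2) |>
    dplyr::mutate(variance = c(1, 2, 4)[match(seed_size, c(1, 2, 4))] / 100)
  res <- match_seed_size(observed, nulls)
  expect_equal(res$per_grid$best_seed, c(2, 2))
  expect_equal(res$mean_seed, 2)
})

test_that("seed-size estimation recovers a boundary (unclustered) layout", {
  lay <- gen_tissue_layout(2000, 0.5, seed_size = 1, rng_seed = 14)
  est <- estimate_seed_size(lay, grids = c(4, 8, 16), seed_sizes = 1:6,
                            n_sim = 100, n_perm = 0, rng_seed = 15)
  expect_lte(est$mean_seed, 2)
})
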