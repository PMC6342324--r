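test_that("population statistics match hand arithmetic", {
  expect_equal(population_stats(counts_tbl(c(2L, 1L, 0L), c(0L, 1L, 2L)))$p_bl6_hat,
               0.5)
  expect_equal(population_stats(counts_tbl(1:3, c(2L, 4L, 6L)))$correlation, 1)
  st <- population_stats(counts_tbl(c(0L, 4L), c(0L, 4L)))
  expect_equal(st$mean_bl6, 2)
  expect_equal(st$var_bl6, 8)
})

test_that("binomial NLL matches closed forms and is minimized at the pooled ratio", {
  expect_equal(binomial_nll(counts_tbl(1L, 1L), 0.5), log(2))
  expect_equal(binomial_nll(counts_tbl(2L, 0L), 0.5), log(4))
  three <- counts_tbl(c(2L, 1L, 0L), c(0L, 1L, 2L))
  expect_equal(binomial_nll(three, 0.5), log(4) + log(2) + log(4))

  cf <- gen_coin_flip_population(generator_config(200, p_bl6 = 0.6,
                                                  rng_seed = 1))
  p_hat <- population_stats(cf)$p_bl6_hat
  grid <- seq(0.05, 0.95, by = 0.005)
  nlls <- vapply(grid, function(p) binomial_nll(cf, p), numeric(1))
  expect_lt(abs(grid[which.min(nlls)] - p_hat), 0.005)
})

test_that("coin-flip test rejects monoallelic data but not its own model", {
  cf <- gen_coin_flip_population(generator_config(500, p_bl6 = 0.6,
                                                  rng_seed = 2))
  fit <- coin_flip_test(cf, n_sims = 500, rng_seed = 3)
  expect_true(fit$percentile > 0.5 && fit$percentile < 99.5)
  expect_true(fit$p_value > 0 && fit$p_value <= 1)

  ao <- gen_all_or_none_population(generator_config(1000, rng_seed = 4))
  power <- coin_flip_test(ao, n_sims = 500, rng_seed = 5)
  expect_gt(power$percentile, 99)

  degenerate <- coin_flip_test(cf, n_sims = 1, rng_seed = 6)
  expect_equal(degenerate$p_value, 1)  # add-one floor
})

test_that("all-or-none assignment follows the majority with fair tie-breaks", {
  expect_equal(all_or_none_assign(counts_tbl(4L, 2L))$n_bl6, 6L)
  expect_equal(all_or_none_assign(counts_tbl(4L, 2L))$n_jf1, 0L)
  kept <- all_or_none_assign(counts_tbl(0L, 3L))
  expect_equal(kept$n_jf1, 3L)

  ties <- all_or_none_assign(counts_tbl(rep(2L, 1e4), rep(2L, 1e4)),
                             rng_seed = 7)
  frac_b <- mean(ties$assigned_identity == "BL6")
  expect_lt(abs(frac_b - 0.5), 0.015)
})

test_that("all-or-none test is self-consistent and keeps population totals", {
  ao <- gen_all_or_none_population(
    generator_config(500, fdr_bl6 = 0.02, fdr_jf1 = 0.02, rng_seed = 8))
  fit <- all_or_none_test(ao, 0.02, 0.02, n_sims = 500, rng_seed = 9)
  expect_true(fit$percentile > 0.5 && fit$percentile < 99.5)
  expect_equal(sum(fit$example_sim$n_bl6), sum(ao$n_bl6))
  expect_equal(sum(fit$example_sim$n_jf1), sum(ao$n_jf1))
})

test_that("noise-free monoallelic input reproduces itself with anticorrelated alleles", {
  ao <- gen_all_or_none_population(generator_config(300, rng_seed = 10))
  fit <- all_or_none_test(ao, 0, 0, n_sims = 50, rng_seed = 11)
  expect_equal(fit$example_sim$n_bl6, ao$n_bl6)
  expect_equal(fit$observed, 0)
  expect_lte(fit$observed_correlation, 0)
})

test_that("coin-flip data yields excess correlation under the all-or-none null", {
  cf <- gen_coin_flip_population(generator_config(1000, rng_seed = 12))
  fit <- all_or_none_test(cf, 0.02, 0.02, n_sims = 500, rng_seed = 13)
  expect_gt(fit$observed_correlation,
            quantile(fit$null_correlation, 0.975))
})

test_that("false-detection rates are estimated from homozygous controls", {
  hom <- counts_tbl(c(96L, 50L), c(2L, 2L))
  expect_equal(estimate_fdr(hom, "BL6"), 4 / 150)
  expect_equal(estimate_fdr(hom, "JF1"), 146 / 150)
})
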