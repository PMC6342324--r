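test_that("coin-flip generator respects degenerate and pooled probabilities", {
  all_b <- gen_coin_flip_population(
    generator_config(200, p_bl6 = 1, rng_seed = 1))
  expect_true(all(all_b$n_jf1 == 0))
  expect_true(all(all_b$n_bl6 == all_b$total))

  big <- gen_coin_flip_population(
    generator_config(1e4, p_bl6 = 0.5, rng_seed = 2))
  pooled <- sum(big$n_bl6) / sum(big$n_bl6 + big$n_jf1)
  expect_lt(abs(pooled - 0.5), 0.02)
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- generator_config(500, p_bl6 = 0.4, fdr_bl6 = 0.05, fdr_jf1 = 0.02,
                          rng_seed = 7)
  expect_identical(gen_coin_flip_population(cfg), gen_coin_flip_population(cfg))
  expect_identical(gen_all_or_none_population(cfg),
                   gen_all_or_none_population(cfg))
  pb <- negbin_from_burst(2, 1.5)
  expect_identical(gen_bursting_population(300, pb, pb, rng_seed = 3),
                   gen_bursting_population(300, pb, pb, rng_seed = 3))
})

test_that("all-or-none generator produces mutually exclusive counts", {
  pop <- gen_all_or_none_population(generator_config(1e4, rng_seed = 4))
  expect_true(all(pop$n_bl6 == 0 | pop$n_jf1 == 0))
  nz <- pop$total > 0
  expect_lte(cor(pop$n_bl6[nz], pop$n_jf1[nz]), 0)
})

test_that("complete false detection swaps identities relative to a clean run", {
  clean <- gen_all_or_none_population(generator_config(300, rng_seed = 5))
  flipped <- gen_all_or_none_population(
    generator_config(300, fdr_bl6 = 1, fdr_jf1 = 1, rng_seed = 5))
  expect_equal(flipped$n_bl6, clean$n_jf1)
  expect_equal(flipped$n_jf1, clean$n_bl6)
})

test_that("bursting generator matches negative-binomial moments and independence", {
  pars <- negbin_params(p = 0.5, r = 2)  # mean 2, variance 4
  pop <- gen_bursting_population(1e5, pars, pars, rng_seed = 6)
  expect_lt(abs(mean(pop$n_bl6) / 2 - 1), 0.02)
  expect_lt(abs(var(pop$n_bl6) / 4 - 1), 0.05)
  pop2 <- gen_bursting_population(1e4, pars, pars, rng_seed = 7)
  expect_lt(abs(cor(pop2$n_bl6, pop2$n_jf1)), 0.05)
})

test_that("bursting approaches the Poisson limit at large burst frequency", {
  # mean fixed at 2, burst size 2/r -> 0
  pars <- negbin_params(p = 1e4 / (1e4 + 2), r = 1e4)
  pop <- gen_bursting_population(1e5, pars, pars, rng_seed = 8)
  expect_lt(abs(var(pop$n_bl6) / mean(pop$n_bl6) - 1), 0.05)
})

test_that("false-detection flips preserve totals and hit the expected split", {
  pop <- counts_tbl(rep(10L, 2000), rep(0L, 2000))
  out <- apply_false_detection(pop, 0.5, 0, rng_seed = 9)
  expect_true(all(out$n_bl6 + out$n_jf1 == 10L))
  expect_lt(abs(mean(out$n_bl6) - 5), 0.15)  # binomial thinning expectation

  ident <- apply_false_detection(pop, 0, 0, rng_seed = 10)
  expect_equal(ident$n_bl6, pop$n_bl6)
  swapped <- apply_false_detection(counts_tbl(3:5, c(1L, 0L, 2L)), 1, 1,
                                   rng_seed = 11)
  expect_equal(swapped$n_bl6, c(1L, 0L, 2L))
  expect_equal(swapped$n_jf1, 3:5)
})

test_that("detection downsampling thins counts and preserves NB structure", {
  pop <- counts_tbl(c(4L, 0L, 7L), c(2L, 3L, 1L))
  same <- apply_detection_downsampling(pop, 1, rng_seed = 12)
  expect_equal(same$n_bl6, pop$n_bl6)
  expect_equal(same$total, as.integer(pop$n_bl6 + pop$n_jf1))

  out <- apply_detection_downsampling(pop, 0.5, rng_seed = 13)
  expect_true(all(out$n_bl6 <= pop$n_bl6 & out$n_jf1 <= pop$n_jf1))

  nb <- gen_bursting_population(1e5, negbin_params(p = 0.5, r = 2),
                                negbin_params(p = 0.5, r = 2), rng_seed = 14)
  thin <- apply_detection_downsampling(nb, 0.5, rng_seed = 15)
  expect_lt(abs(mean(thin$n_bl6) / 1 - 1), 0.03)  # thinned NB mean 0.5 * 2
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(0), class = "allelefish_config_error")
  expect_error(generator_config(10, p_bl6 = 1.2),
               class = "allelefish_config_error")
  expect_error(generator_config(10, total_count_model = list(name = "weird")),
               class = "allelefish_config_error")
  expect_error(
    generator_config(10, total_count_model = list(name = "poisson", lambda = -1)),
    class = "allelefish_config_error")
})
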