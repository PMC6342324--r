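test_that("moments fit matches hand arithmetic and rejects underdispersion", {
  fit <- fit_negbin_moments(c(0, 4))  # impossible: v = 8 > m = 2
  expect_equal(fit$p, 0.25)

  hand <- fit_negbin_moments(c(0, 0, 4, 4))  # m = 2, v = 16/3
  expect_equal(hand$p, 0.375)
  expect_equal(hand$r, 1.2)
  expect_equal(hand$burst_size, (1 - 0.375) / 0.375)

  expect_error(fit_negbin_moments(c(2, 2, 2, 2)),
               class = "allelefish_underdispersed")
  expect_error(fit_negbin_moments(c(0, 0, 0)), "mean must be positive")
})

test_that("moments fit recovers generating burst parameters (round trip)", {
  truth <- negbin_params(p = 1 / 3, r = 1.5)  # burst size 2
  pop <- gen_bursting_population(1e5, truth, truth, rng_seed = 1)
  fit <- fit_negbin_moments(pop, "bl6")
  expect_lt(abs(fit$burst_size / 2 - 1), 0.1)
  expect_lt(abs(fit$burst_frequency / 1.5 - 1), 0.1)
})

test_that("bursting NLL is additive over cells", {
  pars <- negbin_params(p = 0.4, r = 2)
  x <- c(0, 3, 7)
  total <- allelefish:::negbin_nll(x, pars)
  parts <- vapply(x, function(xi) allelefish:::negbin_nll(xi, pars),
                  numeric(1))
  expect_equal(total, sum(parts))
})

test_that("bursting goodness-of-fit accepts its own model and flags Poisson data", {
  pars <- negbin_from_burst(2, 1.5)
  pop <- gen_bursting_population(2000, pars, pars, rng_seed = 2)
  fit <- bursting_fit_test(pop, "bl6", n_sims = 500, rng_seed = 3)
  expect_true(fit$percentile > 0.5 && fit$percentile < 99.5)

  # non-overdispersed (Poisson) counts cannot support a bursting fit
  poisson_counts <- counts_tbl(
    n_bl6 = withr::with_seed(3, rpois(5000, 3)),
    n_jf1 = withr::with_seed(11, rpois(5000, 3)))
  expect_error(fit_negbin_moments(poisson_counts, "bl6"),
               class = "allelefish_underdispersed")
})

test_that("burst-size scan covers the grid and recovers the generating size", {
  pars <- negbin_from_burst(2, 1.5)
  pop <- gen_bursting_population(1e4, pars, pars, rng_seed = 6)
  scan <- burst_size_scan(pop, "bl6", burst_sizes = c(0.5, 1, 2, 3, 5),
                          n_sims = 400, rng_seed = 7)
  expect_equal(scan$burst_size, c(0.5, 1, 2, 3, 5))
  expect_true(scan$good_fit[scan$burst_size == 2])
  expect_false(scan$good_fit[scan$burst_size == 0.5])
  expect_false(scan$good_fit[scan$burst_size == 5])
})

test_that("near-Poisson data prefers the smallest burst size in the scan", {
  x <- withr::with_seed(8, rpois(3000, 3))
  scan <- burst_size_scan(x, burst_sizes = c(0.5, 1, 2, 4), n_sims = 300,
                          rng_seed = 9)
  best <- scan$burst_size[which.min(abs(scan$percentile - 50))]
  expect_equal(best, 0.5)
})

test_that("paired correlation null is centred at zero and detects coupling", {
  pars <- negbin_from_burst(2, 1.5)
  pop <- gen_bursting_population(1000, pars, pars, rng_seed = 10)
  fit <- paired_correlation_test(pop, n_sims = 2000, rng_seed = 11)
  expect_lt(abs(mean(fit$null)), 0.01)

  # positively coupled alleles through a shared per-cell scaling factor
  coupled <- withr::with_seed(12, {
    f <- rgamma(1000, shape = 2, rate = 2)
    counts_tbl(n_bl6 = rpois(1000, 3 * f), n_jf1 = rpois(1000, 3 * f))
  })
  fit2 <- paired_correlation_test(coupled, n_sims = 1000, rng_seed = 13)
  expect_gt(fit2$observed, quantile(fit2$null, 0.975))
})

test_that("false-assignment flips shift the correlation null upward", {
  pop <- gen_bursting_population(1000, negbin_from_burst(2, 2.5),
                                 negbin_from_burst(2, 0.25), rng_seed = 14)
  base <- paired_correlation_test(pop, n_sims = 500, rng_seed = 15)
  noisy <- paired_correlation_test(pop, n_sims = 500, fdr_bl6 = 0.1,
                                   fdr_jf1 = 0.1, rng_seed = 15)
  expect_gt(mean(noisy$null), mean(base$null) + 0.05)
})
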