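## Transcriptional bursting: negative-binomial moments fit, Monte-Carlo
## goodness of fit, burst-size scan, and the paired-correlation null.

#' Method-of-moments negative-binomial fit for one allele
#'
#' Fits the negative binomial by matching the sample mean and sample
#' variance: `p = mean / variance` and `r = mean^2 / (variance - mean)`.
#' Burst size is `(1 - p) / p` and burst frequency is `r`.
#'
#' @param counts A per-cell count table, or a bare numeric vector of counts.
#' @param allele Which allele's counts to fit (`"bl6"` or `"jf1"`); ignored
#'   when `counts` is a vector.
#' @return A [negbin_params()] object carrying the sample moments.
#' @export
#' @examples
#' fit_negbin_moments(c(0, 0, 4, 4))  # p = 0.375, r = 1.2
fit_negbin_moments <- function(counts, allele = c("bl6", "jf1")) {
  x <- if (is.numeric(counts)) {
    counts
  } else {
    allele <- match.arg(allele)
    check_allele_counts(counts)[[paste0("n_", allele)]]
  }
  m <- mean(x)
  v <- var(x)
  if (!isTRUE(m > 0)) abort("Sample mean must be positive.")
  if (!isTRUE(v > m)) {
    abort("Counts are underdispersed (variance <= mean); negative binomial moments are undefined.",
          class = "allelefish_underdispersed")
  }
  negbin_params(p = m / v, r = m^2 / (v - m), mean = m, variance = v)
}

negbin_nll <- function(x, params) {
  -sum(dnbinom(x, size = params$r, prob = params$p, log = TRUE))
}

sim_negbin_nll <- function(n_cells, params, n_sims, chunk = 2000L) {
  unlist(lapply(split(seq_len(n_sims), ceiling(seq_len(n_sims) / chunk)),
                function(idx) {
    k <- length(idx)
    draws <- matrix(rnbinom(n_cells * k, size = params$r, prob = params$p),
                    nrow = n_cells)
    -colSums(dnbinom(draws, size = params$r, prob = params$p, log = TRUE))
  }), use.names = FALSE)
}

#' Monte-Carlo goodness-of-fit test of the negative-binomial bursting model
#'
#' Fits (or takes) negative-binomial parameters for one allele, simulates
#' `n_sims` datasets of the same size from that distribution, and compares
#' the observed negative log-likelihood with the simulated NLL distribution.
#'
#' @inheritParams fit_negbin_moments
#' @param n_sims Number of simulated datasets (default 10,000).
#' @param params Optional [negbin_params()] to use instead of the moments
#'   fit (used by [burst_size_scan()]).
#' @param rng_seed Optional integer seed.
#' @return An `allele_model_test` (statistic `"nll"`) with extra field
#'   `params`.
#' @export
bursting_fit_test <- function(counts, allele = c("bl6", "jf1"),
                              n_sims = 10000, params = NULL,
                              rng_seed = NULL) {
  allele <- match.arg(allele)
  x <- if (is.numeric(counts)) counts else {
    check_allele_counts(counts)[[paste0("n_", allele)]]
  }
  n_sims <- assert_count(n_sims, "n_sims")
  if (is.null(params)) params <- fit_negbin_moments(x)
  observed <- negbin_nll(x, params)
  null <- with_seed(rng_seed, sim_negbin_nll(length(x), params, n_sims))
  new_model_test("bursting", "nll", observed, null, n_sims, rng_seed,
                 params = params, allele = allele)
}

#' Scan burst sizes for compatibility with one allele's counts
#'
#' Re-parameterizes the negative binomial over a grid of burst sizes while
#' holding the observed sample mean fixed (`p = 1 / (1 + b)`, `r = mean / b`)
#' and runs the Monte-Carlo goodness-of-fit test at each burst size. A burst
#' size is a "good fit" when the observed NLL lies within the central 95% of
#' its simulated NLL distribution.
#'
#' @inheritParams bursting_fit_test
#' @param burst_sizes Burst sizes to test (default 0.5 to 5 in steps of 0.5).
#' @return A tibble of class `burst_scan`: `burst_size`, `burst_frequency`,
#'   `observed_nll`, `null_mean`, `percentile`, `p_value`, `good_fit`.
#' @export
burst_size_scan <- function(counts, allele = c("bl6", "jf1"),
                            burst_sizes = seq(0.5, 5, by = 0.5),
                            n_sims = 10000, rng_seed = NULL) {
  allele <- match.arg(allele)
  x <- if (is.numeric(counts)) counts else {
    check_allele_counts(counts)[[paste0("n_", allele)]]
  }
  m <- mean(x)
  if (!isTRUE(m > 0)) abort("Sample mean must be positive.")
  out <- purrr::map_dfr(seq_along(burst_sizes), function(i) {
    b <- burst_sizes[i]
    params <- negbin_params(p = 1 / (1 + b), r = m / b)
    fit <- bursting_fit_test(x, n_sims = n_sims, params = params,
                             rng_seed = child_seed(rng_seed, i))
    tibble::tibble(burst_size = b, burst_frequency = params$r,
                   observed_nll = fit$observed, null_mean = mean(fit$null),
                   percentile = fit$percentile, p_value = fit$p_value,
                   good_fit = fit$percentile >= 2.5 & fit$percentile <= 97.5)
  })
  class(out) <- c("burst_scan", class(out))
  out
}

## Pearson correlation of paired columns of two matrices.
col_correlations <- function(a, b) {
  n <- nrow(a)
  ma <- colMeans(a); mb <- colMeans(b)
  cov_ab <- colMeans(a * b) - ma * mb
  va <- colMeans(a^2) - ma^2
  vb <- colMeans(b^2) - mb^2
  cov_ab / sqrt(va * vb)
}

#' Null distribution of the BL6-JF1 correlation under independent bursting
#'
#' Draws per-cell counts for the two alleles independently from their
#' negative-binomial fits, pairs them randomly into "cells", optionally
#' applies one round of false-detection identity flips, and computes the
#' Pearson correlation per simulation. The observed per-cell correlation is
#' located in this null.
#'
#' @param counts A per-cell count table (used for the observed correlation,
#'   the number of cells, and the default moments fits).
#' @param params_bl6,params_jf1 Optional [negbin_params()] overriding the
#'   moments fits.
#' @param n_sims Number of simulations (default 10,000).
#' @param fdr_bl6,fdr_jf1 Per-RNA false-detection flip rates applied once per
#'   simulation (default 0 = no noise).
#' @param rng_seed Optional integer seed.
#' @return An `allele_model_test` (statistic `"correlation"`).
#' @export
paired_correlation_test <- function(counts, params_bl6 = NULL,
                                    params_jf1 = NULL, n_sims = 10000,
                                    fdr_bl6 = 0, fdr_jf1 = 0,
                                    rng_seed = NULL) {
  counts <- check_allele_counts(counts)
  n_sims <- assert_count(n_sims, "n_sims")
  assert_prob(fdr_bl6, "fdr_bl6")
  assert_prob(fdr_jf1, "fdr_jf1")
  if (is.null(params_bl6)) params_bl6 <- fit_negbin_moments(counts, "bl6")
  if (is.null(params_jf1)) params_jf1 <- fit_negbin_moments(counts, "jf1")
  n <- nrow(counts)
  nz <- counts$n_bl6 + counts$n_jf1 > 0
  observed <- suppressWarnings(cor(counts$n_bl6[nz], counts$n_jf1[nz]))

  null <- with_seed(rng_seed, {
    chunk <- max(1L, min(n_sims, as.integer(2e6 / n)))
    unlist(lapply(split(seq_len(n_sims), ceiling(seq_len(n_sims) / chunk)),
                  function(idx) {
      k <- length(idx)
      b <- matrix(rnbinom(n * k, size = params_bl6$r, prob = params_bl6$p),
                  nrow = n)
      j <- matrix(rnbinom(n * k, size = params_jf1$r, prob = params_jf1$p),
                  nrow = n)
      if (fdr_bl6 > 0 || fdr_jf1 > 0) {
        flip_b <- matrix(rbinom(n * k, b, fdr_bl6), nrow = n)
        flip_j <- matrix(rbinom(n * k, j, fdr_jf1), nrow = n)
        b2 <- b - flip_b + flip_j
        j <- j - flip_j + flip_b
        b <- b2
      }
      col_correlations(b, j)
    }), use.names = FALSE)
  })
  new_model_test("bursting_correlation", "correlation", observed, null,
                 n_sims, rng_seed,
                 params_bl6 = params_bl6, params_jf1 = params_jf1,
                 fdr_bl6 = fdr_bl6, fdr_jf1 = fdr_jf1)
}
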