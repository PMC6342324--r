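## Monte-Carlo likelihood tests of the three generative models of single-cell
## allelic imbalance: the coin-flip binomial null, the all-or-none
## (random monoallelic) model, and (in negbin.R) independent
## negative-binomial bursting.

new_model_test <- function(model, statistic, observed, null, n_sims,
                           rng_seed = NULL, ...) {
  structure(
    c(list(model = model, statistic = statistic, observed = observed,
           null = null,
           percentile = empirical_percentile(observed, null),
           p_value = empirical_p_value(observed, null),
           n_sims = n_sims, rng_seed = rng_seed),
      list(...)),
    class = "allele_model_test")
}

#' @export
print.allele_model_test <- function(x, ...) {
  cat(sprintf("<allele_model_test> %s model, %s statistic\n", x$model,
              x$statistic))
  cat(sprintf("  observed %.4f | null %.4f +/- %.4f (%d sims)\n",
              x$observed, mean(x$null), sd(x$null), x$n_sims))
  cat(sprintf("  percentile %.1f, two-sided empirical p = %.4g\n",
              x$percentile, x$p_value))
  invisible(x)
}

#' Population-level summary of a per-cell allelic count table
#'
#' Computes the pooled BL6 fraction `p_bl6_hat` (total BL6 RNAs over all
#' assigned RNAs), per-allele means and sample variances, and the Pearson
#' correlation of per-cell (BL6, JF1) counts. Cells with zero assigned RNAs
#' are excluded from the correlation (they carry no allelic information) but
#' kept in the moments.
#'
#' @param counts A per-cell count table with columns `n_bl6`, `n_jf1`.
#' @return A one-row tibble: `n_cells`, `p_bl6_hat`, `mean_bl6`, `var_bl6`,
#'   `mean_jf1`, `var_jf1`, `correlation`.
#' @export
#' @examples
#' population_stats(tibble::tibble(n_bl6 = c(2, 1, 0), n_jf1 = c(0, 1, 2)))
population_stats <- function(counts) {
  counts <- check_allele_counts(counts)
  if (nrow(counts) < 2) abort("Need at least 2 cells.")
  pooled <- sum(counts$n_bl6) + sum(counts$n_jf1)
  if (pooled == 0) abort("Pooled allelic total is zero; cannot estimate the allelic ratio.")
  nz <- counts$n_bl6 + counts$n_jf1 > 0
  tibble::tibble(
    n_cells = nrow(counts),
    p_bl6_hat = sum(counts$n_bl6) / pooled,
    mean_bl6 = mean(counts$n_bl6), var_bl6 = var(counts$n_bl6),
    mean_jf1 = mean(counts$n_jf1), var_jf1 = var(counts$n_jf1),
    correlation = if (sum(nz) >= 2) {
      suppressWarnings(cor(counts$n_bl6[nz], counts$n_jf1[nz]))
    } else NA_real_
  )
}

#' Negative log-likelihood of counts under the coin-flip binomial model
#'
#' Under the coin-flip model each cell's BL6 count is
#' Binomial(n_bl6 + n_jf1, `p_bl6`). Cells with zero assigned RNAs contribute
#' nothing.
#'
#' @param counts A per-cell count table.
#' @param p_bl6 The shared per-RNA BL6 probability.
#' @return The scalar negative log-likelihood. Infinite (with a warning) when
#'   `p_bl6` is 0 or 1 but incompatible counts are present.
#' @export
#' @examples
#' binomial_nll(tibble::tibble(n_bl6 = 1, n_jf1 = 1), 0.5)  # log(2)
binomial_nll <- function(counts, p_bl6) {
  counts <- check_allele_counts(counts)
  assert_prob(p_bl6, "p_bl6")
  tot <- counts$n_bl6 + counts$n_jf1
  nll <- -sum(dbinom(counts$n_bl6, tot, p_bl6, log = TRUE))
  if (!is.finite(nll)) {
    warn("Binomial NLL is infinite: some counts are impossible at this p_bl6.")
  }
  nll
}

## Null NLL distribution for the coin-flip model: redraw each cell's BL6
## count conditional on its observed total, n_sims times, in memory chunks.
sim_coin_flip_nll <- function(tot, p, n_sims, chunk = 2000L) {
  n <- length(tot)
  unlist(lapply(split(seq_len(n_sims), ceiling(seq_len(n_sims) / chunk)),
                function(idx) {
    k <- length(idx)
    draws <- matrix(rbinom(n * k, tot, p), nrow = n)
    -colSums(dbinom(draws, tot, p, log = TRUE))
  }), use.names = FALSE)
}

#' Monte-Carlo goodness-of-fit test of the coin-flip model
#'
#' Estimates the population allelic ratio, simulates `n_sims` datasets by
#' redrawing each cell's BL6 count from Binomial(observed total, p_bl6_hat),
#' and locates the observed negative log-likelihood within the simulated NLL
#' distribution.
#'
#' @param counts A per-cell count table.
#' @param n_sims Number of simulated datasets (default 10,000).
#' @param rng_seed Optional integer seed.
#' @return An object of class `allele_model_test` (see [tidy()] /
#'   [glance()] methods).
#' @export
#' @examples
#' cf <- gen_coin_flip_population(generator_config(200, rng_seed = 1))
#' coin_flip_test(cf, n_sims = 200, rng_seed = 2)
coin_flip_test <- function(counts, n_sims = 10000, rng_seed = NULL) {
  counts <- check_allele_counts(counts)
  n_sims <- assert_count(n_sims, "n_sims")
  p_hat <- population_stats(counts)$p_bl6_hat
  observed <- binomial_nll(counts, p_hat)
  tot <- counts$n_bl6 + counts$n_jf1
  null <- with_seed(rng_seed, sim_coin_flip_nll(tot, p_hat, n_sims))
  new_model_test("coin_flip", "nll", observed, null, n_sims, rng_seed,
                 p_bl6_hat = p_hat)
}

#' Idealized all-or-none assignment of per-cell counts
#'
#' Reassigns every RNA in a cell to the cell's majority identity; exact ties
#' are resolved by a fair coin. A cell with 4 BL6 and 2 JF1 RNAs becomes a
#' BL6 cell with 6 BL6 RNAs. Per-cell totals are preserved.
#'
#' @param counts A per-cell count table.
#' @param rng_seed Optional integer seed (used only for tie cells).
#' @return The count table with monoallelic `n_bl6`/`n_jf1` and a new
#'   `assigned_identity` column ("BL6"/"JF1").
#' @export
#' @examples
#' all_or_none_assign(tibble::tibble(n_bl6 = 4, n_jf1 = 2))
all_or_none_assign <- function(counts, rng_seed = NULL) {
  counts <- check_allele_counts(counts)
  with_seed(rng_seed, {
    tot <- counts$n_bl6 + counts$n_jf1
    is_bl6 <- counts$n_bl6 > counts$n_jf1
    ties <- counts$n_bl6 == counts$n_jf1
    is_bl6[ties] <- runif(sum(ties)) < 0.5
    dplyr::mutate(counts,
                  assigned_identity = ifelse(is_bl6, "BL6", "JF1"),
                  n_bl6 = as.integer(ifelse(is_bl6, tot, 0L)),
                  n_jf1 = as.integer(ifelse(is_bl6, 0L, tot)))
  })
}

## Per-identity flip counts (kB: BL6->JF1, kJ: JF1->BL6) for the
## all-or-none noise simulations. kB is drawn from the exact conditional
## distribution of Binomial(nb_ideal, fdr_bl6) given that
## kB - kJ equals the net flip `d` required to reproduce the observed
## population totals, with kJ ~ Binomial(nj_ideal, fdr_jf1) independently:
##   P(kB = k | kB - kJ = d) proportional to
##   dbinom(k; nb_ideal, fdr_bl6) * dbinom(k - d; nj_ideal, fdr_jf1).
## This keeps the per-identity flip rates at the measured false-detection
## rates (in conditional expectation) while satisfying the constraint in
## every draw. Returns `n` draws of kB; kJ = kB - d.
draw_flip_counts <- function(n, nb_ideal, nj_ideal, fdr_bl6, fdr_jf1, d) {
  lo <- max(d, 0)
  hi <- min(nb_ideal, nj_ideal + d)
  if (lo > hi) {
    abort("Population-total constraint is infeasible for these false-detection rates and totals.")
  }
  support <- lo:hi
  lw <- dbinom(support, nb_ideal, fdr_bl6, log = TRUE) +
    dbinom(support - d, nj_ideal, fdr_jf1, log = TRUE)
  if (all(!is.finite(lw))) {
    abort("Required flip counts are impossible at these false-detection rates (zero rate but nonzero net flips needed).")
  }
  w <- exp(lw - max(lw[is.finite(lw)]))
  if (length(support) == 1L) {
    rep(support, n)
  } else {
    sample(support, n, replace = TRUE, prob = w)
  }
}

## Spread `k` flips over cells with sizes `sizes` uniformly without
## replacement (multivariate hypergeometric via index sampling).
spread_flips <- function(k, sizes) {
  if (k == 0 || length(sizes) == 0) return(integer(length(sizes)))
  cells <- findInterval(sample.int(sum(sizes), k), cumsum(sizes),
                        left.open = TRUE) + 1L
  tabulate(cells, length(sizes))
}

## Two-subpopulation binomial NLL: cells are grouped by majority identity
## (exact ties by fair coin unless `is_b` is supplied); within BL6 cells the
## minority (JF1) count is Binomial(total, fdr_bl6), and symmetrically.
two_group_nll <- function(b, j, tot, fdr_bl6, fdr_jf1, is_b = NULL) {
  if (is.null(is_b)) {
    is_b <- b > j
    ties <- b == j
    if (any(ties)) is_b[ties] <- runif(sum(ties)) < 0.5
  }
  -sum(dbinom(j[is_b], tot[is_b], fdr_bl6, log = TRUE)) -
    sum(dbinom(b[!is_b], tot[!is_b], fdr_jf1, log = TRUE))
}

#' Monte-Carlo test of the all-or-none (random monoallelic) model
#'
#' Starts from the idealized all-or-none assignment of the observed counts,
#' then simulates technical noise `n_sims` times: RNAs flip to the opposite
#' identity at the false-detection rates measured in homozygous controls,
#' under the constraint that the simulated population totals of BL6 and JF1
#' RNAs exactly equal the observed totals. The negative log-likelihood uses
#' two separate binomial nulls: within BL6-assigned cells the minority (JF1)
#' count is Binomial(total, `fdr_bl6`), and symmetrically for JF1 cells.
#' The Pearson correlation of simulated (BL6, JF1) counts is also recorded.
#'
#' @param counts A per-cell count table.
#' @param fdr_bl6,fdr_jf1 False-detection rates measured in BL6 and JF1
#'   homozygous populations.
#' @param n_sims Number of noise simulations (default 10,000).
#' @param rng_seed Optional integer seed.
#' @return An `allele_model_test` (statistic `"nll"`), with extra fields
#'   `null_correlation` (simulated correlations), `observed_correlation`,
#'   and `example_sim` (one simulated population).
#' @export
all_or_none_test <- function(counts, fdr_bl6, fdr_jf1, n_sims = 10000,
                             rng_seed = NULL) {
  counts <- check_allele_counts(counts)
  assert_prob(fdr_bl6, "fdr_bl6", allow_one = FALSE)
  assert_prob(fdr_jf1, "fdr_jf1", allow_one = FALSE)
  n_sims <- assert_count(n_sims, "n_sims")

  ideal <- all_or_none_assign(counts, rng_seed = child_seed(rng_seed, 1))
  tot <- counts$n_bl6 + counts$n_jf1
  is_b <- ideal$assigned_identity == "BL6"
  nb_ideal <- sum(tot[is_b]); nj_ideal <- sum(tot[!is_b])
  nb_obs <- sum(counts$n_bl6)
  d <- nb_ideal - nb_obs  # net BL6 -> JF1 flips needed

  ## observed NLL under the two-subpopulation binomial noise model
  observed <- two_group_nll(counts$n_bl6, counts$n_jf1, tot,
                            fdr_bl6, fdr_jf1, is_b = is_b)
  if (!is.finite(observed)) {
    warn("Observed all-or-none NLL is infinite (minority RNAs present at a zero false-detection rate).")
  }
  nz <- tot > 0
  observed_cor <- if (sum(nz) >= 2) {
    suppressWarnings(cor(counts$n_bl6[nz], counts$n_jf1[nz]))
  } else NA_real_

  sizes_b <- tot[is_b]; sizes_j <- tot[!is_b]

  null_nll <- numeric(n_sims)
  null_cor <- numeric(n_sims)
  example_sim <- NULL
  sim_b <- numeric(length(tot))
  with_seed(child_seed(rng_seed, 2), {
    k_b_draws <- draw_flip_counts(n_sims, nb_ideal, nj_ideal,
                                  fdr_bl6, fdr_jf1, d)
    for (s in seq_len(n_sims)) {
      f_b <- spread_flips(k_b_draws[s], sizes_b)      # BL6->JF1 per BL6 cell
      f_j <- spread_flips(k_b_draws[s] - d, sizes_j)  # JF1->BL6 per JF1 cell
      sim_b[is_b] <- sizes_b - f_b
      sim_b[!is_b] <- f_j
      sim_j <- tot - sim_b
      ## each simulated population is pushed through the same majority
      ## re-assignment as the observed data before its NLL is evaluated,
      ## so the two are exchangeable under the model (a parametric
      ## bootstrap; without this, fully flipped low-count cells depress
      ## the observed NLL relative to the null)
      null_nll[s] <- two_group_nll(sim_b, sim_j, tot, fdr_bl6, fdr_jf1)
      null_cor[s] <- if (sum(nz) >= 2) {
        suppressWarnings(cor(sim_b[nz], sim_j[nz]))
      } else NA_real_
      if (s == n_sims) {
        example_sim <- new_allele_counts(sim_b, sim_j,
                                         cell_id = counts$cell_id)
      }
    }
  })
  new_model_test("all_or_none", "nll", observed, null_nll, n_sims, rng_seed,
                 null_correlation = null_cor,
                 observed_correlation = observed_cor,
                 fdr_bl6 = fdr_bl6, fdr_jf1 = fdr_jf1,
                 example_sim = example_sim)
}

#' Estimate a false-detection rate from a homozygous control population
#'
#' In homozygous tissue every RNA has a known true identity, so the
#' false-detection rate is the fraction of uniquely assigned RNAs that carry
#' the wrong identity.
#'
#' @param counts A per-cell count table from homozygous tissue.
#' @param true_identity Which allele the tissue is homozygous for
#'   (`"BL6"` or `"JF1"`).
#' @return The estimated false-detection rate (scalar in `[0, 1]`).
#' @export
estimate_fdr <- function(counts, true_identity = c("BL6", "JF1")) {
  counts <- check_allele_counts(counts)
  true_identity <- match.arg(true_identity)
  wrong <- if (true_identity == "BL6") sum(counts$n_jf1) else sum(counts$n_bl6)
  total <- sum(counts$n_bl6) + sum(counts$n_jf1)
  if (total == 0) abort("No uniquely assigned RNAs in the control population.")
  wrong / total
}
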