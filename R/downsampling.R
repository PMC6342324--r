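## Detection-efficiency robustness: rerun the coin-flip or all-or-none
## simulation at each cell's full RNA total, thin each simulated cell back to
## its uniquely assigned count, and compare the resulting null distributions
## with the direct (non-downsampled) simulation.

## Hypergeometric thinning of simulated (BL6, JF1) splits: of tot RNAs of
## which b are BL6, keep `keep` drawn without replacement.
thin_split <- function(b, tot, keep) {
  rhyper(length(b), m = b, n = tot - b, k = keep)
}

#' Robustness of model verdicts to the colocalization (detection) rate
#'
#' Only about half of guide spots typically receive a unique allelic
#' identity, so model tests run on assigned counts are implicitly
#' downsampled. This check repeats the chosen model's simulation at each
#' cell's full RNA total (`total` column), randomly downsamples every
#' simulated cell to the number of RNAs that were uniquely assigned in the
#' original measurement (hypergeometric thinning), and compares the
#' downsampled null NLL distribution with the direct simulation by a
#' two-sample Kolmogorov-Smirnov test. For the all-or-none model the
#' simulated correlation distributions are compared as well.
#'
#' @param counts A per-cell count table with a `total` column
#'   (`total >= n_bl6 + n_jf1`).
#' @param model `"coin_flip"` or `"all_or_none"`.
#' @param fdr_bl6,fdr_jf1 False-detection rates (all-or-none model only).
#' @param n_sims Simulations per run (default 5,000).
#' @param rng_seed Optional integer seed; the direct and downsampled runs
#'   share the simulation stream so they are draw-for-draw identical when
#'   `total` equals the assigned count everywhere.
#' @return A list of class `downsampling_robustness`: `direct` and
#'   `downsampled` (`allele_model_test`s), `ks_nll` (statistic, p-value) and,
#'   for the all-or-none model, `ks_correlation`.
#' @export
downsampling_robustness <- function(counts,
                                    model = c("coin_flip", "all_or_none"),
                                    fdr_bl6 = 0, fdr_jf1 = 0,
                                    n_sims = 5000, rng_seed = NULL) {
  model <- match.arg(model)
  counts <- check_allele_counts(counts, require_total = TRUE)
  n_sims <- assert_count(n_sims, "n_sims")
  assigned <- counts$n_bl6 + counts$n_jf1
  tot <- counts$total
  no_thinning <- all(tot == assigned)

  if (model == "coin_flip") {
    direct <- coin_flip_test(counts, n_sims = n_sims,
                             rng_seed = child_seed(rng_seed, 1))
    p_hat <- direct$p_bl6_hat
    n <- nrow(counts)
    down_null <- with_seed(child_seed(rng_seed, 1), {
      vapply(seq_len(n_sims), function(s) {
        full_b <- rbinom(n, tot, p_hat)
        kept_b <- if (no_thinning) full_b else {
          thin_split(full_b, tot, assigned)
        }
        -sum(dbinom(kept_b, assigned, p_hat, log = TRUE))
      }, numeric(1))
    })
    downsampled <- new_model_test("coin_flip_downsampled", "nll",
                                  direct$observed, down_null, n_sims,
                                  rng_seed, p_bl6_hat = p_hat)
    ks <- suppressWarnings(ks.test(direct$null, down_null))
    structure(list(model = model, direct = direct, downsampled = downsampled,
                   ks_nll = c(statistic = unname(ks$statistic),
                              p_value = unname(ks$p.value))),
              class = "downsampling_robustness")
  } else {
    direct <- all_or_none_test(counts, fdr_bl6, fdr_jf1, n_sims = n_sims,
                               rng_seed = child_seed(rng_seed, 1))
    ## full-scale run: every RNA in the cell (assigned or not) takes the
    ## cell's identity; the population constraint is scaled to the full
    ## totals at the observed allelic ratio
    p_hat <- population_stats(counts)$p_bl6_hat
    ## reuse the direct run's majority identities (same assignment seed)
    ideal <- all_or_none_assign(counts,
                                rng_seed = child_seed(child_seed(rng_seed, 1), 1))
    is_b <- ideal$assigned_identity == "BL6"
    full_b_tot <- round(p_hat * sum(tot))
    ## draw noise at full scale with the population constraint rescaled to
    ## the full totals at the observed ratio, then thin each simulated cell
    ## back to its assigned count
    nb_ideal <- sum(tot[is_b]); nj_ideal <- sum(tot[!is_b])
    d <- nb_ideal - full_b_tot
    sizes_b <- tot[is_b]; sizes_j <- tot[!is_b]
    n <- nrow(counts)
    nz <- assigned > 0
    down_nll <- numeric(n_sims)
    down_cor <- numeric(n_sims)
    sim_b <- numeric(n)
    ## share the direct run's simulation stream so the two runs coincide
    ## draw-for-draw when no thinning is needed
    with_seed(child_seed(child_seed(rng_seed, 1), 2), {
      k_b_draws <- draw_flip_counts(n_sims, nb_ideal, nj_ideal,
                                    fdr_bl6, fdr_jf1, d)
      for (s in seq_len(n_sims)) {
        f_b <- spread_flips(k_b_draws[s], sizes_b)
        f_j <- spread_flips(k_b_draws[s] - d, sizes_j)
        sim_b[is_b] <- sizes_b - f_b
        sim_b[!is_b] <- f_j
        kept_b <- if (no_thinning) sim_b else {
          thin_split(sim_b, tot, assigned)
        }
        kept_j <- assigned - kept_b
        ## same majority re-assignment pipeline as the direct test
        down_nll[s] <- two_group_nll(kept_b, kept_j, assigned,
                                     fdr_bl6, fdr_jf1)
        down_cor[s] <- if (sum(nz) >= 2) {
          suppressWarnings(cor(kept_b[nz], kept_j[nz]))
        } else NA_real_
      }
    })
    downsampled <- new_model_test("all_or_none_downsampled", "nll",
                                  direct$observed, down_nll, n_sims, rng_seed,
                                  null_correlation = down_cor,
                                  observed_correlation = direct$observed_correlation,
                                  fdr_bl6 = fdr_bl6, fdr_jf1 = fdr_jf1)
    ks <- suppressWarnings(ks.test(direct$null, down_nll))
    ks_cor <- suppressWarnings(ks.test(direct$null_correlation, down_cor))
    structure(list(model = model, direct = direct, downsampled = downsampled,
                   ks_nll = c(statistic = unname(ks$statistic),
                              p_value = unname(ks$p.value)),
                   ks_correlation = c(statistic = unname(ks_cor$statistic),
                                      p_value = unname(ks_cor$p.value))),
              class = "downsampling_robustness")
  }
}

#' @export
print.downsampling_robustness <- function(x, ...) {
  cat(sprintf("<downsampling_robustness> %s model, %d sims\n", x$model,
              x$direct$n_sims))
  cat(sprintf("  KS(NLL direct vs downsampled): D = %.4f, p = %.4g\n",
              x$ks_nll[["statistic"]], x$ks_nll[["p_value"]]))
  if (!is.null(x$ks_correlation)) {
    cat(sprintf("  KS(correlation): D = %.4f, p = %.4g\n",
                x$ks_correlation[["statistic"]],
                x$ks_correlation[["p_value"]]))
  }
  invisible(x)
}
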