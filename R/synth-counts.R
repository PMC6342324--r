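#' Configuration for synthetic per-cell allelic count generators
#'
#' Bundles the parameters shared by the count-table generators: the number of
#' cells, the distribution of per-cell total RNA counts, the population
#' allelic ratio, per-allele false-detection rates and an overall detection
#' efficiency. The default total-count model is Poisson with mean 3 RNAs per
#' cell, matching the low-count regime of allele-resolved transcripts in
#' kidney tissue (measured means of roughly 2.6-3.5 per cell).
#'
#' @param n_cells Number of cells to simulate (integer >= 1).
#' @param total_count_model Either `list(name = "poisson", lambda = <mean>)`
#'   or `list(name = "empirical", counts = <integer vector>)`; per-cell totals
#'   are drawn from this distribution (empirical = resampling with
#'   replacement).
#' @param p_bl6 Population probability that an RNA carries the BL6 (C57BL/6J)
#'   identity, in `[0, 1]`.
#' @param fdr_bl6,fdr_jf1 Per-RNA false-detection probabilities: the chance
#'   that a truly BL6 (respectively JF1) RNA is assigned the opposite
#'   identity. Measured in homozygous control tissue in a real experiment.
#' @param detection_rate Probability in `(0, 1]` that an RNA is detected at
#'   all; used by [apply_detection_downsampling()].
#' @param rng_seed Optional integer seed; every generator is bit-reproducible
#'   under a fixed seed.
#'
#' @return A validated list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_cells = 100, p_bl6 = 0.6, rng_seed = 1)
generator_config <- function(n_cells,
                             total_count_model = list(name = "poisson", lambda = 3),
                             p_bl6 = 0.5,
                             fdr_bl6 = 0,
                             fdr_jf1 = 0,
                             detection_rate = 1,
                             rng_seed = NULL) {
  n_cells <- assert_count(n_cells, "n_cells")
  assert_prob(p_bl6, "p_bl6")
  assert_prob(fdr_bl6, "fdr_bl6")
  assert_prob(fdr_jf1, "fdr_jf1")
  assert_prob(detection_rate, "detection_rate", allow_zero = FALSE)
  if (!is.list(total_count_model) || is.null(total_count_model$name) ||
      !total_count_model$name %in% c("poisson", "empirical")) {
    abort("`total_count_model` must be list(name = \"poisson\", lambda = ...) or list(name = \"empirical\", counts = ...).",
          class = "allelefish_config_error")
  }
  if (total_count_model$name == "poisson") {
    assert_pos(total_count_model$lambda %||% NULL, "total_count_model$lambda")
  } else {
    counts <- total_count_model$counts
    if (is.null(counts) || !is.numeric(counts) || length(counts) == 0 ||
        any(counts < 0) || any(counts != floor(counts))) {
      abort("`total_count_model$counts` must be a non-empty vector of non-negative integers.",
            class = "allelefish_config_error")
    }
  }
  structure(list(n_cells = n_cells, total_count_model = total_count_model,
                 p_bl6 = p_bl6, fdr_bl6 = fdr_bl6, fdr_jf1 = fdr_jf1,
                 detection_rate = detection_rate, rng_seed = rng_seed),
            class = "generator_config")
}

draw_totals <- function(cfg) {
  m <- cfg$total_count_model
  if (m$name == "poisson") {
    stats::rpois(cfg$n_cells, m$lambda)
  } else {
    sample(as.integer(m$counts), cfg$n_cells, replace = TRUE)
  }
}

#' Simulate a coin-flip (binomial) cell population
#'
#' Under the coin-flip scenario every detected RNA draws its allelic identity
#' independently with probability `p_bl6` of being BL6, irrespective of which
#' cell it sits in. Per cell, the total count comes from the configured
#' total-count model and the BL6 count is Binomial(total, p_bl6).
#'
#' @param cfg A [generator_config()].
#' @return A tibble with columns `cell_id`, `n_bl6`, `n_jf1`, `n_unassigned`,
#'   `n_dual` and `total`.
#' @export
#' @examples
#' gen_coin_flip_population(generator_config(5, p_bl6 = 0.5, rng_seed = 1))
gen_coin_flip_population <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$rng_seed, {
    totals <- draw_totals(cfg)
    n_bl6 <- rbinom(cfg$n_cells, totals, cfg$p_bl6)
    new_allele_counts(n_bl6, totals - n_bl6, total = totals)
  })
}

#' Simulate an all-or-none (random monoallelic) cell population
#'
#' Each cell independently commits to one allele (BL6 with probability
#' `p_bl6`); all its RNAs carry that identity. Technical noise is then
#' applied: each RNA flips to the opposite identity with the false-detection
#' rate of its true identity (`fdr_bl6` for BL6 RNAs, `fdr_jf1` for JF1).
#'
#' @inheritParams gen_coin_flip_population
#' @return A tibble of per-cell counts; the extra column `true_identity`
#'   records each cell's committed allele ("BL6"/"JF1") before noise.
#' @export
gen_all_or_none_population <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$rng_seed, {
    totals <- draw_totals(cfg)
    is_bl6 <- runif(cfg$n_cells) < cfg$p_bl6
    # noise-free monoallelic counts
    n_bl6 <- ifelse(is_bl6, totals, 0L)
    n_jf1 <- totals - n_bl6
    # per-RNA identity flips at the rate of the RNA's true identity
    flip_b <- rbinom(cfg$n_cells, n_bl6, cfg$fdr_bl6)
    flip_j <- rbinom(cfg$n_cells, n_jf1, cfg$fdr_jf1)
    out <- new_allele_counts(n_bl6 - flip_b + flip_j,
                             n_jf1 - flip_j + flip_b,
                             total = totals)
    out$true_identity <- ifelse(is_bl6, "BL6", "JF1")
    out
  })
}

#' Parameters of a negative-binomial transcript-count distribution
#'
#' The two-state (bursting) promoter model is summarised by a negative
#' binomial with parameters `p` and `r`; the mean is `r (1 - p) / p` and the
#' variance `r (1 - p) / p^2`. Burst size is `(1 - p) / p` (RNAs per burst)
#' and burst frequency is `r` (bursts per RNA lifetime).
#'
#' @param p Success probability in `(0, 1)`.
#' @param r Dispersion (number of failures), > 0.
#' @param mean,variance Optional sample moments to carry along (set by
#'   [fit_negbin_moments()]).
#' @return An object of class `negbin_params`.
#' @seealso [negbin_from_burst()] to parameterize by burst size/frequency.
#' @export
negbin_params <- function(p, r, mean = r * (1 - p) / p,
                          variance = r * (1 - p) / p^2) {
  assert_prob(p, "p", allow_zero = FALSE, allow_one = FALSE)
  assert_pos(r, "r")
  structure(list(p = p, r = r,
                 burst_size = (1 - p) / p, burst_frequency = r,
                 mean = mean, variance = variance),
            class = "negbin_params")
}

#' @param burst_size Mean RNAs per transcriptional burst, > 0.
#' @param burst_frequency Burst rate `r`, > 0.
#' @rdname negbin_params
#' @export
negbin_from_burst <- function(burst_size, burst_frequency) {
  assert_pos(burst_size, "burst_size")
  assert_pos(burst_frequency, "burst_frequency")
  negbin_params(p = 1 / (1 + burst_size), r = burst_frequency)
}

#' @export
print.negbin_params <- function(x, ...) {
  cat(sprintf(
    "<negbin_params> p = %.4g, r = %.4g (burst size %.4g, frequency %.4g; mean %.4g, variance %.4g)\n",
    x$p, x$r, x$burst_size, x$burst_frequency, x$mean, x$variance))
  invisible(x)
}

#' Simulate independently bursting alleles
#'
#' Draws each allele's per-cell count independently from its own negative
#' binomial distribution, so the two alleles are uncorrelated by
#' construction. This is the generative model behind the transcriptional
#' bursting scenario.
#'
#' @param n_cells Number of cells.
#' @param params_bl6,params_jf1 [negbin_params()] for each allele.
#' @param rng_seed Optional integer seed.
#' @return A tibble of per-cell counts (`total` = sum of the two draws).
#' @export
gen_bursting_population <- function(n_cells, params_bl6, params_jf1,
                                    rng_seed = NULL) {
  n_cells <- assert_count(n_cells, "n_cells")
  stopifnot(inherits(params_bl6, "negbin_params"),
            inherits(params_jf1, "negbin_params"))
  with_seed(rng_seed, {
    n_bl6 <- rnbinom(n_cells, size = params_bl6$r, prob = params_bl6$p)
    n_jf1 <- rnbinom(n_cells, size = params_jf1$r, prob = params_jf1$p)
    new_allele_counts(n_bl6, n_jf1, total = n_bl6 + n_jf1)
  })
}

#' Apply per-RNA false-detection flips to a count table
#'
#' Each RNA independently flips to the opposite allelic identity with the
#' false-detection rate of its current identity. Per-cell totals are
#' unchanged; only the split between `n_bl6` and `n_jf1` moves.
#'
#' @param counts A per-cell count table (columns `n_bl6`, `n_jf1`).
#' @param fdr_bl6,fdr_jf1 Flip probabilities in `[0, 1]`.
#' @param rng_seed Optional integer seed.
#' @return The count table with flipped counts.
#' @export
apply_false_detection <- function(counts, fdr_bl6, fdr_jf1, rng_seed = NULL) {
  counts <- check_allele_counts(counts)
  assert_prob(fdr_bl6, "fdr_bl6")
  assert_prob(fdr_jf1, "fdr_jf1")
  with_seed(rng_seed, {
    flip_b <- rbinom(nrow(counts), counts$n_bl6, fdr_bl6)
    flip_j <- rbinom(nrow(counts), counts$n_jf1, fdr_jf1)
    dplyr::mutate(counts,
                  n_bl6 = .data$n_bl6 - flip_b + flip_j,
                  n_jf1 = .data$n_jf1 - flip_j + flip_b)
  })
}

#' Thin a count table to a given detection efficiency
#'
#' Each RNA is retained independently with probability `detection_rate`
#' (binomial thinning, applied to every count column). The `total` column is
#' set to the pre-thinning total so downstream detection-efficiency analyses
#' ([downsampling_robustness()]) can recover the original cell sizes.
#'
#' @param counts A per-cell count table.
#' @param detection_rate Retention probability in `(0, 1]`.
#' @param rng_seed Optional integer seed.
#' @return The thinned count table with a `total` column holding the
#'   pre-thinning per-cell totals.
#' @export
apply_detection_downsampling <- function(counts, detection_rate,
                                         rng_seed = NULL) {
  counts <- check_allele_counts(counts)
  assert_prob(detection_rate, "detection_rate", allow_zero = FALSE)
  pre_total <- if ("total" %in% names(counts)) {
    counts$total
  } else {
    rowSums(counts[intersect(c("n_bl6", "n_jf1", "n_unassigned", "n_dual"),
                             names(counts))])
  }
  with_seed(rng_seed, {
    out <- counts
    for (col in intersect(c("n_bl6", "n_jf1", "n_unassigned", "n_dual"),
                          names(out))) {
      out[[col]] <- rbinom(nrow(out), out[[col]], detection_rate)
    }
    out$total <- as.integer(pre_total)
    out
  })
}
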