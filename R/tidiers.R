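## broom-style tidiers for the package's result objects.

#' Tidy the null distribution of a Monte-Carlo model test
#'
#' @param x An `allele_model_test`.
#' @param ... Unused.
#' @return A tibble with one row per simulation: `sim`, `value` (the null
#'   statistic) and `statistic` (its name).
#' @export
tidy.allele_model_test <- function(x, ...) {
  tibble::tibble(sim = seq_along(x$null), statistic = x$statistic,
                 value = x$null)
}

#' One-row summary of a Monte-Carlo model test
#'
#' @param x An `allele_model_test`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `statistic`, `observed`, `null_mean`,
#'   `null_sd`, `percentile`, `p_value`, `n_sims`.
#' @export
glance.allele_model_test <- function(x, ...) {
  tibble::tibble(model = x$model, statistic = x$statistic,
                 observed = x$observed,
                 null_mean = mean(x$null[!is.na(x$null)]),
                 null_sd = sd(x$null[!is.na(x$null)]),
                 percentile = x$percentile, p_value = x$p_value,
                 n_sims = x$n_sims)
}

#' @export
tidy.negbin_params <- function(x, ...) {
  tibble::tibble(p = x$p, r = x$r, burst_size = x$burst_size,
                 burst_frequency = x$burst_frequency,
                 mean = x$mean, variance = x$variance)
}

#' @export
tidy.seed_match <- function(x, ...) {
  x$per_grid
}

#' @export
glance.seed_match <- function(x, ...) {
  tibble::tibble(mean_seed = x$mean_seed, sd_seed = x$sd_seed,
                 n_grids = nrow(x$per_grid))
}

#' @export
tidy.coloc_result <- function(x, ...) {
  x$guides
}

#' @export
glance.coloc_result <- function(x, ...) {
  tibble::tibble(n_guide = x$n_guide, radius = x$radius,
                 overall_coloc = x$rates[["overall_coloc"]],
                 unique_coloc = x$rates[["unique_coloc"]])
}

#' @export
tidy.radius_scan <- function(x, ...) {
  x$scan
}

#' @export
glance.radius_scan <- function(x, ...) {
  chosen <- x$scan[x$scan$radius == x$chosen_radius, ]
  tibble::tibble(chosen_radius = x$chosen_radius,
                 real_overall = chosen$real_overall,
                 shifted_overall = chosen$shifted_overall,
                 objective = chosen$objective)
}

#' @export
tidy.spatial_variance <- function(x, ...) {
  x$tiles
}

#' @export
glance.spatial_variance <- function(x, ...) {
  tibble::tibble(rows = x$grid[["rows"]], cols = x$grid[["cols"]],
                 n_occupied = x$n_occupied, variance = x$variance)
}

#' @export
tidy.foci_classification <- function(x, ...) {
  x$foci
}

#' @export
glance.foci_classification <- function(x, ...) {
  tibble::tibble(n_foci = nrow(x$foci),
                 critical_angle = x$critical_angle,
                 n_bl6 = sum(x$foci$assignment == "BL6"),
                 n_jf1 = sum(x$foci$assignment == "JF1"))
}

#' @export
glance.downsampling_robustness <- function(x, ...) {
  tibble::tibble(model = x$model,
                 ks_nll_statistic = x$ks_nll[["statistic"]],
                 ks_nll_p = x$ks_nll[["p_value"]],
                 ks_cor_statistic = if (!is.null(x$ks_correlation)) {
                   x$ks_correlation[["statistic"]]
                 } else NA_real_,
                 ks_cor_p = if (!is.null(x$ks_correlation)) {
                   x$ks_correlation[["p_value"]]
                 } else NA_real_)
}
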