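## ggplot2 visualizations of the package's result objects.

#' Plot a Monte-Carlo null distribution with the observed statistic
#'
#' @param object An `allele_model_test`.
#' @param bins Histogram bins (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allele_model_test <- function(object, bins = 50, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = if (object$statistic == "nll") {
        "negative log-likelihood"
      } else "Pearson correlation",
      y = "simulations",
      title = sprintf("%s model: observed at percentile %.1f (p = %.3g)",
                      object$model, object$percentile, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a colocalization radius scan
#'
#' Real and pixel-shifted overall colocalization rates against the matching
#' radius, with the chosen radius marked.
#'
#' @param object A `radius_scan` from [select_radius()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radius_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(object$scan,
                            c("real_overall", "shifted_overall"),
                            names_to = "series", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius, y = .data$rate,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$chosen_radius,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(real_overall = "black", shifted_overall = "grey55"),
      labels = c(real_overall = "real", shifted_overall = "pixel-shifted")) +
    ggplot2::labs(x = "radius (px)", y = "overall colocalization rate",
                  colour = NULL,
                  title = sprintf("chosen radius %.2f px",
                                  object$chosen_radius)) +
    ggplot2::theme_minimal()
}

#' Plot observed grid variances against the seeded-cluster nulls
#'
#' One panel per grid: mean simulated variance (+/- sd) by seed size, the
#' observed variance as a horizontal line, and the matched seed marked.
#'
#' @param object A `seed_match` from [estimate_seed_size()] or
#'   [match_seed_size()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seed_match <- function(object, ...) {
  nm <- object$null_means
  obs <- object$per_grid
  ggplot2::ggplot(nm, ggplot2::aes(x = .data$seed_size,
                                   y = .data$mean_variance)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_variance - .data$sd_variance,
      ymax = .data$mean_variance + .data$sd_variance), fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = obs,
                        ggplot2::aes(yintercept = .data$observed_variance),
                        colour = "red") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$best_seed),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~grid, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "seed size (cells per cluster)",
                  y = "variance of per-rectangle BL6 fraction",
                  title = sprintf("mean matched seed %.2f (sd %.2f)",
                                  object$mean_seed, object$sd_seed)) +
    ggplot2::theme_minimal()
}

#' Plot a burst-size scan
#'
#' @param object A `burst_scan` from [burst_size_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burst_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$burst_size,
                                       y = .data$percentile,
                                       colour = .data$good_fit)) +
    ggplot2::geom_hline(yintercept = c(2.5, 97.5), linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "burst size (RNAs per burst)",
                  y = "observed NLL percentile in null",
                  colour = "good fit") +
    ggplot2::theme_minimal()
}

#' Scatter plot of per-cell allelic counts
#'
#' Jittered per-cell BL6 vs JF1 counts, the standard view of single-cell
#' allelic imbalance.
#'
#' @param counts A per-cell count table.
#' @param jitter_width Jitter amplitude in RNA units (default 0.2).
#' @return A ggplot object.
#' @export
plot_allelic_scatter <- function(counts, jitter_width = 0.2) {
  counts <- check_allele_counts(counts)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$n_bl6, y = .data$n_jf1)) +
    ggplot2::geom_jitter(width = jitter_width, height = jitter_width,
                         alpha = 0.4) +
    ggplot2::labs(x = "BL6 RNAs per cell", y = "JF1 RNAs per cell") +
    ggplot2::theme_minimal()
}

#' Plot a classified angle distribution
#'
#' @param object A `foci_classification`.
#' @param bins Histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.foci_classification <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object$foci, ggplot2::aes(x = .data$theta,
                                            fill = .data$assignment)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(xintercept = object$critical_angle,
                        linetype = "dashed") +
    ggplot2::labs(x = "intensity-ratio angle (rad)", y = "foci",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
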