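#' Specification of a synthetic three-channel spot field
#'
#' Describes a guide-channel spot field plus two allele channels with a
#' shared chromatic offset, localization jitter and uniform spurious spots.
#' Emulates the regime measured in tissue, where somewhat over half of guide
#' spots gain a unique allele-specific partner.
#'
#' @param image_extent Field size `c(width, height)` in pixels.
#' @param n_guide Number of guide spots.
#' @param chromatic_shift 2D offset (pixels) applied to the allele channels
#'   relative to the guide channel.
#' @param localization_jitter_sd Isotropic Gaussian localization error (px).
#' @param coloc_prob_bl6,coloc_prob_jf1 Probability that a guide spot has a
#'   BL6 (resp. JF1) partner; their sum must be <= 1.
#' @param spurious_density Spurious spots per pixel^2, added uniformly to
#'   each allele channel.
#' @param cell_grid Tiling `c(rows, cols)` used to assign guides a `cell_id`.
#' @param rng_seed Optional integer seed.
#' @return A validated list of class `spot_field_spec`.
#' @export
spot_field_spec <- function(image_extent = c(512, 512), n_guide = 500,
                            chromatic_shift = c(0, 0),
                            localization_jitter_sd = 0,
                            coloc_prob_bl6 = 0.3, coloc_prob_jf1 = 0.3,
                            spurious_density = 0, cell_grid = c(5, 5),
                            rng_seed = NULL) {
  n_guide <- assert_count(n_guide, "n_guide", min = 0L)
  assert_prob(coloc_prob_bl6, "coloc_prob_bl6")
  assert_prob(coloc_prob_jf1, "coloc_prob_jf1")
  if (coloc_prob_bl6 + coloc_prob_jf1 > 1) {
    abort("`coloc_prob_bl6 + coloc_prob_jf1` must be <= 1.",
          class = "allelefish_config_error")
  }
  if (spurious_density < 0 || localization_jitter_sd < 0) {
    abort("Densities and jitter must be non-negative.",
          class = "allelefish_config_error")
  }
  structure(list(image_extent = image_extent, n_guide = n_guide,
                 chromatic_shift = chromatic_shift,
                 localization_jitter_sd = localization_jitter_sd,
                 coloc_prob_bl6 = coloc_prob_bl6,
                 coloc_prob_jf1 = coloc_prob_jf1,
                 spurious_density = spurious_density,
                 cell_grid = cell_grid, rng_seed = rng_seed),
            class = "spot_field_spec")
}

new_spot_table <- function(channel, x, y, z = 0, intensity = NULL,
                           cell_id = NA_integer_) {
  n <- length(x)
  tibble::tibble(channel = rep_len(channel, n), x = x, y = y,
                 z = rep_len(z, n),
                 intensity = if (is.null(intensity)) {
                   runif(n, 800, 1200)
                 } else rep_len(intensity, n),
                 cell_id = rep_len(cell_id, n))
}

#' Generate a synthetic three-channel spot field with ground truth
#'
#' Guide spots are uniform in the field; each independently gains a BL6 or
#' JF1 partner with the configured probabilities, displaced by the chromatic
#' shift plus Gaussian jitter. Spurious spots are sprinkled uniformly into
#' the allele channels. Guides are assigned `cell_id`s by tiling the field.
#'
#' @param spec A [spot_field_spec()].
#' @return A list with spot tables `guide`, `bl6`, `jf1` (columns `channel`,
#'   `x`, `y`, `z`, `intensity`, `cell_id`) and `truth` (per guide:
#'   `guide_id`, `cell_id`, `true_assignment` in BL6/JF1/none).
#' @export
#' @examples
#' field <- gen_spot_field(spot_field_spec(n_guide = 100, rng_seed = 1))
#' table(field$truth$true_assignment)
gen_spot_field <- function(spec) {
  stopifnot(inherits(spec, "spot_field_spec"))
  w <- spec$image_extent[1]; h <- spec$image_extent[2]
  with_seed(spec$rng_seed, {
    n <- spec$n_guide
    gx <- runif(n, 0, w); gy <- runif(n, 0, h)
    cell_id <- as.integer(
      (pmin(spec$cell_grid[1], ceiling(gy / (h / spec$cell_grid[1]) + 1e-12)) - 1L) *
        spec$cell_grid[2] +
        pmin(spec$cell_grid[2], ceiling(gx / (w / spec$cell_grid[2]) + 1e-12)))
    u <- runif(n)
    assignment <- ifelse(u < spec$coloc_prob_bl6, "BL6",
                         ifelse(u < spec$coloc_prob_bl6 + spec$coloc_prob_jf1,
                                "JF1", "none"))
    partner_xy <- function(keep) {
      k <- sum(keep)
      list(x = gx[keep] + spec$chromatic_shift[1] +
             rnorm(k, 0, spec$localization_jitter_sd),
           y = gy[keep] + spec$chromatic_shift[2] +
             rnorm(k, 0, spec$localization_jitter_sd))
    }
    spurious_xy <- function() {
      k <- stats::rpois(1, spec$spurious_density * w * h)
      list(x = runif(k, 0, w), y = runif(k, 0, h))
    }
    b <- partner_xy(assignment == "BL6"); sb <- spurious_xy()
    j <- partner_xy(assignment == "JF1"); sj <- spurious_xy()
    list(
      guide = new_spot_table("guide", gx, gy, cell_id = cell_id),
      bl6 = new_spot_table("bl6", c(b$x, sb$x), c(b$y, sb$y)),
      jf1 = new_spot_table("jf1", c(j$x, sj$x), c(j$y, sj$y)),
      truth = tibble::tibble(guide_id = seq_len(n), cell_id = cell_id,
                             true_assignment = assignment)
    )
  })
}
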