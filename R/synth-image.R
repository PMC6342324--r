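## Synthetic single-plane foci images: well-separated 2D Gaussian blobs on a
## noisy constant background, with ground truth. The point-spread function is
## modelled as an isotropic Gaussian.

place_separated <- function(n, extent, min_sep, margin, max_tries = 200) {
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      px <- runif(1, 1 + margin, extent[1] - margin)
      py <- runif(1, 1 + margin, extent[2] - margin)
      if (length(xs) == 0 ||
          min((xs - px)^2 + (ys - py)^2) >= min_sep^2) {
        xs <- c(xs, px); ys <- c(ys, py); placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("Could not place %d foci at separation >= %.1f px in a %dx%d field.",
                    n, min_sep, extent[1], extent[2]),
            class = "allelefish_config_error")
    }
  }
  list(x = xs, y = ys)
}

## Add Gaussian blobs to an image matrix (first index x, second y).
add_blobs <- function(img, x, y, amplitude, psf_sd) {
  half <- ceiling(5 * psf_sd)
  for (i in seq_along(x)) {
    ix <- max(1, floor(x[i] - half)):min(nrow(img), ceiling(x[i] + half))
    iy <- max(1, floor(y[i] - half)):min(ncol(img), ceiling(y[i] + half))
    gx <- exp(-(ix - x[i])^2 / (2 * psf_sd^2))
    gy <- exp(-(iy - y[i])^2 / (2 * psf_sd^2))
    img[ix, iy] <- img[ix, iy] + amplitude[i] * outer(gx, gy)
  }
  img
}

#' Generate a synthetic foci image with ground truth
#'
#' Places `n_foci` Gaussian blobs (sd `psf_sd`) at random positions at least
#' `4 * psf_sd` apart (rejection placement, with a border margin so every
#' blob lies in the interior), on a constant background with additive
#' Gaussian noise.
#'
#' @param n_foci Number of foci (>= 0).
#' @param extent Image size `c(width, height)` in pixels.
#' @param psf_sd Gaussian point-spread sd in pixels.
#' @param intensity_range Range `c(lo, hi)` of peak amplitudes, drawn
#'   uniformly per focus.
#' @param background_level Constant background intensity.
#' @param noise_sd SD of the additive Gaussian pixel noise.
#' @param rng_seed Optional integer seed.
#' @return A list: `image` (numeric matrix, first index x) and `truth`
#'   (tibble `focus_id`, `x`, `y`, `amplitude`).
#' @export
#' @examples
#' im <- gen_foci_image(5, extent = c(128, 128), rng_seed = 1)
#' nrow(im$truth)
gen_foci_image <- function(n_foci, extent = c(256, 256), psf_sd = 2,
                           intensity_range = c(800, 1200),
                           background_level = 100, noise_sd = 5,
                           rng_seed = NULL) {
  n_foci <- assert_count(n_foci, "n_foci", min = 0L)
  assert_pos(psf_sd, "psf_sd")
  with_seed(rng_seed, {
    pos <- place_separated(n_foci, extent, min_sep = 4 * psf_sd,
                           margin = 5 * psf_sd)
    amplitude <- runif(n_foci, intensity_range[1], intensity_range[2])
    img <- matrix(background_level, extent[1], extent[2])
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(extent[1] * extent[2], 0, noise_sd),
                          extent[1], extent[2])
    }
    img <- add_blobs(img, pos$x, pos$y, amplitude, psf_sd)
    list(image = img,
         truth = tibble::tibble(focus_id = seq_len(n_foci),
                                x = pos$x, y = pos$y,
                                amplitude = amplitude))
  })
}

#' Render an image for a truth table of foci
#'
#' Renders blobs at the positions of an existing truth table with
#' user-supplied per-focus amplitudes; used to build co-registered SNV
#' channels for the same foci.
#'
#' @param truth A truth tibble from [gen_foci_image()] (columns `x`, `y`).
#' @param amplitude Per-focus peak amplitudes (recycled).
#' @inheritParams gen_foci_image
#' @return A numeric image matrix.
#' @export
render_foci_image <- function(truth, amplitude, extent = c(256, 256),
                              psf_sd = 2, background_level = 100,
                              noise_sd = 5, rng_seed = NULL) {
  with_seed(rng_seed, {
    img <- matrix(background_level, extent[1], extent[2])
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(extent[1] * extent[2], 0, noise_sd),
                          extent[1], extent[2])
    }
    add_blobs(img, truth$x, truth$y,
              rep_len(amplitude, nrow(truth)), psf_sd)
  })
}
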