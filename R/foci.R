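## Detection of bright RNA foci in a guide-channel image and allelic
## classification from the two SNV-channel intensity ratio.

#' Detection parameters for guide-channel foci
#'
#' @param background_sigma SD (px) of the large Gaussian blur used as the
#'   background estimate (default 10x the LoG sigma).
#' @param log_sigma SD (px) of the Laplacian-of-Gaussian blob filter; match
#'   to the expected focus radius.
#' @param threshold_nsd Binarization threshold in robust noise-SD units
#'   (median absolute deviations of the LoG response above zero).
#' @param min_intensity Minimum mean background-subtracted guide intensity
#'   per component.
#' @param min_solidity Minimum solidity (component area / convex hull area).
#' @param min_area,max_area Component area bounds in px^2.
#' @return A validated list of class `detection_params`.
#' @export
detection_params <- function(log_sigma = 2,
                             background_sigma = 10 * log_sigma,
                             threshold_nsd = 6,
                             min_intensity = 0,
                             min_solidity = 0.8,
                             min_area = 4,
                             max_area = 500) {
  assert_pos(log_sigma, "log_sigma")
  assert_pos(background_sigma, "background_sigma")
  assert_pos(threshold_nsd, "threshold_nsd")
  if (min_area >= max_area) {
    abort("`min_area` must be smaller than `max_area`.",
          class = "allelefish_config_error")
  }
  structure(list(log_sigma = log_sigma, background_sigma = background_sigma,
                 threshold_nsd = threshold_nsd, min_intensity = min_intensity,
                 min_solidity = min_solidity, min_area = min_area,
                 max_area = max_area),
            class = "detection_params")
}

## Grayscale morphological opening (erosion then dilation) over a 3x3
## diamond, via shifted pmin/pmax with replicated edges. EBImage's
## opening() is binary-only, so this is done by hand.
shift_pad <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  xs <- pmin(pmax(seq_len(nx) + dx, 1), nx)
  ys <- pmin(pmax(seq_len(ny) + dy, 1), ny)
  m[xs, ys]
}

gray_open <- function(m, offsets = cbind(c(0, 1, -1, 0, 0),
                                         c(0, 0, 0, 1, -1))) {
  er <- m
  for (i in seq_len(nrow(offsets))) {
    er <- pmin(er, shift_pad(m, offsets[i, 1], offsets[i, 2]))
  }
  di <- er
  for (i in seq_len(nrow(offsets))) {
    di <- pmax(di, shift_pad(er, offsets[i, 1], offsets[i, 2]))
  }
  di
}

## Laplacian-of-Gaussian kernel, sign-flipped so bright blobs give positive
## responses; zero-mean so flat regions map to zero.
log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  ax <- -half:half
  g <- exp(-ax^2 / (2 * sigma^2))
  r2 <- outer(ax^2, ax^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^4 * outer(g, g)
  k - mean(k)
}

## Convex-hull area of a set of pixel centers (shoelace), floored at 1.
hull_area <- function(px, py) {
  if (length(unique(paste(px, py))) < 3) return(length(px))
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  max(a, 1)
}

#' Detect bright foci in a guide-channel image
#'
#' Pipeline: subtract a large-sigma Gaussian blur (background estimate),
#' grayscale morphological opening (removes sub-resolution speckle),
#' Laplacian-of-Gaussian filtering (sharpens blob-scale structure),
#' binarization at a robust noise threshold, connected components, border
#' clearing, and component filters (area bounds, minimum solidity, minimum
#' mean intensity).
#'
#' @param image A 2D numeric matrix (first index x) or EBImage `Image`.
#' @param params A [detection_params()].
#' @return A tibble of class `foci_table` with columns `focus_id`, `x`, `y`
#'   (intensity-weighted centroid), `area`, `solidity`, `guide_intensity`
#'   (mean background-subtracted intensity). The component label matrix is
#'   attached as attribute `labels` (with `label_ids` mapping rows to
#'   labels) for downstream intensity measurement.
#' @export
#' @examples
#' im <- gen_foci_image(10, extent = c(200, 200), rng_seed = 1)
#' nrow(detect_foci(im$image))
detect_foci <- function(image, params = detection_params()) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (!is.matrix(image)) abort("`image` must be a 2D numeric matrix.")
  empty <- tibble::tibble(focus_id = integer(), x = numeric(),
                          y = numeric(), area = integer(),
                          solidity = numeric(), guide_intensity = numeric())
  class(empty) <- c("foci_table", class(empty))
  if (length(image) == 0) return(empty)

  ## background subtraction
  bg <- EBImage::gblur(image, sigma = params$background_sigma)
  sub <- image - bg
  ## grayscale morphological opening to remove sub-resolution speckle and
  ## smooth boundaries
  opened <- gray_open(sub)
  ## LoG sharpening
  resp <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(opened), log_kernel(params$log_sigma)))
  ## robust threshold in noise-SD units
  th <- params$threshold_nsd * mad(resp, center = 0)
  mask <- resp > th
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  n_lab <- max(labels)
  if (n_lab == 0) {
    attr(empty, "labels") <- labels
    return(empty)
  }
  ## border clearing: drop components touching the frame edge
  border_labs <- unique(c(labels[1, ], labels[nrow(labels), ],
                          labels[, 1], labels[, ncol(labels)]))
  keep_border <- setdiff(seq_len(n_lab), border_labs)

  idx <- which(labels > 0)
  lab <- labels[idx]
  px <- (idx - 1) %% nrow(labels) + 1
  py <- (idx - 1) %/% nrow(labels) + 1
  w <- pmax(sub[idx], 0)

  stats <- tibble::tibble(lab = lab, px = px, py = py, w = w) |>
    dplyr::filter(.data$lab %in% keep_border) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(
      area = dplyr::n(),
      x = sum(.data$px * .data$w) / sum(.data$w),
      y = sum(.data$py * .data$w) / sum(.data$w),
      guide_intensity = mean(.data$w),
      solidity = min(1, dplyr::n() / hull_area(.data$px, .data$py)),
      .groups = "drop") |>
    dplyr::filter(.data$area >= params$min_area,
                  .data$area <= params$max_area,
                  .data$solidity >= params$min_solidity,
                  .data$guide_intensity >= params$min_intensity)
  out <- tibble::tibble(focus_id = seq_len(nrow(stats)),
                        x = stats$x, y = stats$y,
                        area = as.integer(stats$area),
                        solidity = stats$solidity,
                        guide_intensity = stats$guide_intensity)
  class(out) <- c("foci_table", class(out))
  attr(out, "labels") <- labels
  attr(out, "label_ids") <- stats$lab
  attr(out, "background") <- bg
  out
}

#' Measure SNV-channel intensities for detected foci
#'
#' For every focus, takes the mean pixel intensity over its component mask
#' in each SNV channel, subtracts a local background (median of the pixels
#' in an expanded bounding box around the component, excluding all
#' components), normalizes by the whole-image mean of that channel, clips
#' negatives to zero, and computes the intensity-ratio angle
#' `theta = atan2(jf1, bl6)` in `[0, pi/2]`.
#'
#' @param foci A `foci_table` from [detect_foci()] (must carry its label
#'   matrix attribute).
#' @param bl6_image,jf1_image SNV-channel images co-registered with the
#'   guide image.
#' @param pad Pixels of bounding-box expansion for the local background
#'   (default 6).
#' @return The foci table with added columns `bl6_intensity`,
#'   `jf1_intensity` and `theta`.
#' @export
measure_snv_intensities <- function(foci, bl6_image, jf1_image, pad = 6) {
  labels <- attr(foci, "labels")
  ids <- attr(foci, "label_ids")
  if (is.null(labels) || is.null(ids)) {
    abort("`foci` must come from detect_foci() (label matrix attribute missing).")
  }
  if (inherits(bl6_image, "Image")) bl6_image <- EBImage::imageData(bl6_image)
  if (inherits(jf1_image, "Image")) jf1_image <- EBImage::imageData(jf1_image)
  stopifnot(all(dim(bl6_image) == dim(labels)),
            all(dim(jf1_image) == dim(labels)))

  measure_one <- function(img, id) {
    in_mask <- labels == id
    idx <- which(in_mask)
    px <- (idx - 1) %% nrow(labels) + 1
    py <- (idx - 1) %/% nrow(labels) + 1
    rx <- max(1, min(px) - pad):min(nrow(labels), max(px) + pad)
    ry <- max(1, min(py) - pad):min(ncol(labels), max(py) + pad)
    local <- img[rx, ry][labels[rx, ry] == 0]
    bg <- if (length(local) > 0) median(local) else median(img)
    (mean(img[idx]) - bg) / mean(img)
  }
  bl6 <- vapply(ids, function(id) measure_one(bl6_image, id), numeric(1))
  jf1 <- vapply(ids, function(id) measure_one(jf1_image, id), numeric(1))
  out <- dplyr::mutate(foci,
                       bl6_intensity = pmax(bl6, 0),
                       jf1_intensity = pmax(jf1, 0),
                       theta = atan2(pmax(jf1, 0), pmax(bl6, 0)))
  ## a focus dark in both channels has an undefined angle; park it on the
  ## BL6 axis rather than dropping it
  out$theta[out$bl6_intensity == 0 & out$jf1_intensity == 0] <- 0
  attr(out, "labels") <- labels
  attr(out, "label_ids") <- ids
  out
}

#' Classify foci into BL6/JF1 by two-cluster partitioning of the angle
#'
#' Runs 1D k-means (k = 2, multiple restarts under a fixed seed) on the
#' intensity-ratio angles; the critical angle is the midpoint of the two
#' cluster centers. Foci with `theta` above the critical angle are assigned
#' JF1 identity, the rest BL6.
#'
#' @param foci A foci table with a `theta` column (from
#'   [measure_snv_intensities()], or any tibble with `theta`).
#' @param rng_seed Seed for the k-means restarts (default 1; the result is
#'   deterministic under a fixed seed).
#' @return A list of class `foci_classification`: `foci` (the table with an
#'   `assignment` column), `critical_angle`, `centers` (sorted cluster
#'   centers).
#' @export
#' @examples
#' foci <- tibble::tibble(theta = c(0.1, 0.15, 1.3, 1.4))
#' classify_by_kmeans(foci)$critical_angle
classify_by_kmeans <- function(foci, rng_seed = 1) {
  if (!"theta" %in% names(foci)) abort("`foci` must have a `theta` column.")
  theta <- foci$theta
  if (length(theta) < 2) abort("Need at least 2 foci to classify.")
  if (diff(range(theta)) == 0) {
    abort("All intensity-ratio angles are identical: single cluster; cannot classify.")
  }
  centers <- if (length(unique(theta)) == 2) {
    # exactly two distinct angles: the optimal 2-means are those values
    # (base kmeans refuses k = nrow(x))
    sort(unique(theta))
  } else {
    km <- with_seed(rng_seed, kmeans(theta, centers = 2, nstart = 10))
    sort(as.numeric(km$centers))
  }
  critical <- mean(centers)
  out <- dplyr::mutate(tibble::as_tibble(foci),
                       assignment = ifelse(.data$theta > critical,
                                           "JF1", "BL6"))
  structure(list(foci = out, critical_angle = critical, centers = centers),
            class = "foci_classification")
}

#' @export
print.foci_classification <- function(x, ...) {
  cat(sprintf("<foci_classification> %d foci, critical angle %.3f rad (%d BL6, %d JF1)\n",
              nrow(x$foci), x$critical_angle,
              sum(x$foci$assignment == "BL6"),
              sum(x$foci$assignment == "JF1")))
  invisible(x)
}
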