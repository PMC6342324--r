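test_that("blank images yield no foci", {
  blank <- gen_foci_image(0, extent = c(128, 128), rng_seed = 1)
  expect_equal(nrow(detect_foci(blank$image)), 0)
})

test_that("well-separated bright foci are all recovered without false positives", {
  im <- gen_foci_image(50, extent = c(512, 512), psf_sd = 2, rng_seed = 2)
  foci <- detect_foci(im$image)
  expect_gte(nrow(foci), 48)
  d <- sqrt(outer(im$truth$x, foci$x, "-")^2 +
              outer(im$truth$y, foci$y, "-")^2)
  expect_equal(sum(apply(d, 2, min) > 3), 0)     # no false positives
  expect_true(all(apply(d, 1, min)[apply(d, 1, min) < 3] < 1))  # centroid accuracy
})

test_that("component filters exclude oversized foci", {
  im <- gen_foci_image(10, extent = c(300, 300), psf_sd = 2, rng_seed = 3)
  narrow <- detect_foci(im$image, detection_params(max_area = 10))
  full <- detect_foci(im$image)
  expect_lt(nrow(narrow), nrow(full))
  expect_true(all(narrow$area <= 10))
})

test_that("detection is translation-equivariant for interior foci", {
  im <- gen_foci_image(8, extent = c(256, 256), psf_sd = 2, rng_seed = 4)
  shifted <- matrix(100, 256, 256)
  shifted[21:256, 11:256] <- im$image[1:236, 1:246]
  a <- detect_foci(im$image)
  b <- detect_foci(shifted)
  interior <- a[a$x < 230 & a$y < 240, ]
  bb <- b[b$x > 22 & b$y > 12, ]
  d <- sqrt(outer(interior$x + 20, bb$x, "-")^2 +
              outer(interior$y + 10, bb$y, "-")^2)
  expect_true(all(apply(d, 1, min) < 0.5))
})

test_that("SNV intensity angles hit the analytic axis and ratio cases", {
  # large frame so the blobs barely perturb the scan-mean normalization
  im <- gen_foci_image(10, extent = c(600, 600), psf_sd = 2, noise_sd = 0,
                       rng_seed = 5)
  foci <- detect_foci(im$image)
  bl6_only <- render_foci_image(im$truth, 600, extent = c(600, 600),
                                noise_sd = 0, rng_seed = 6)
  dark <- matrix(100, 600, 600)
  m <- measure_snv_intensities(foci, bl6_only, dark)
  expect_true(all(m$theta == 0))  # no JF1 signal at all

  equal <- measure_snv_intensities(foci, bl6_only, bl6_only)
  expect_equal(equal$theta, rep(pi / 4, nrow(foci)))

  three_to_one <- measure_snv_intensities(
    foci, bl6_only,
    render_foci_image(im$truth, 200, extent = c(600, 600), noise_sd = 0,
                      rng_seed = 7))
  expect_lt(max(abs(three_to_one$theta / atan(1 / 3) - 1)), 0.01)
})

test_that("theta is invariant to a common intensity scale", {
  imgs <- make_foci_images(n = 20, extent = c(300, 300), seed = 8)
  foci <- detect_foci(imgs$guide)
  a <- measure_snv_intensities(foci, imgs$bl6, imgs$jf1)
  b <- measure_snv_intensities(foci, imgs$bl6 * 3.7, imgs$jf1 * 3.7)
  expect_equal(a$theta, b$theta, tolerance = 1e-8)
})

test_that("two-cluster classification finds the critical angle", {
  two <- classify_by_kmeans(tibble::tibble(theta = c(0.1, 1.4)))
  expect_equal(two$critical_angle, 0.75)
  expect_equal(two$foci$assignment, c("BL6", "JF1"))

  thetas <- withr::with_seed(9, c(rnorm(500, 0.2, 0.1), rnorm(500, 1.2, 0.1)))
  cls <- classify_by_kmeans(tibble::tibble(theta = pmax(thetas, 0)))
  truth <- rep(c("BL6", "JF1"), each = 500)
  expect_gte(mean(cls$foci$assignment == truth), 0.99)
})

test_that("classification is symmetric under channel swap", {
  thetas <- withr::with_seed(10, c(rnorm(100, 0.2, 0.05), rnorm(100, 1.2, 0.05)))
  cls <- classify_by_kmeans(tibble::tibble(theta = thetas))
  swapped <- classify_by_kmeans(tibble::tibble(theta = pi / 2 - thetas))
  relabeled <- ifelse(swapped$foci$assignment == "BL6", "JF1", "BL6")
  expect_equal(cls$foci$assignment, relabeled)
})

test_that("degenerate angle sets cannot be classified", {
  expect_error(classify_by_kmeans(tibble::tibble(theta = 0.5)), "at least 2")
  expect_error(classify_by_kmeans(tibble::tibble(theta = rep(0.5, 10))),
               "single cluster")
})
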