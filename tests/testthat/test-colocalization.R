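test_that("Gaussian refinement recovers subpixel and integer centers", {
  patch <- allelefish:::add_blobs(matrix(10, 15, 17), 5.3, 7.8, 100, 1.5)
  fit <- refine_spot_center(patch)
  expect_true(fit$converged)
  expect_lt(abs(fit$x - 5.3), 0.02)
  expect_lt(abs(fit$y - 7.8), 0.02)

  centered <- allelefish:::add_blobs(matrix(0, 11, 11), 6, 6, 50, 2)
  fit2 <- refine_spot_center(centered)
  expect_lt(abs(fit2$x - 6), 1e-3)
  expect_lt(abs(fit2$y - 6), 1e-3)
})

test_that("flat patches fall back to the flagged geometric centroid", {
  fit <- refine_spot_center(matrix(7, 9, 9))
  expect_false(fit$converged)
  expect_equal(fit$x, 5)
  expect_equal(fit$y, 5)
})

test_that("displacement estimation recovers a constant offset", {
  guide <- tibble::tibble(x = runif(30, 10, 90), y = runif(30, 10, 90))
  allele <- dplyr::mutate(guide, x = x + 0.4, y = y - 0.3)
  d <- estimate_displacement(guide, allele)
  expect_equal(d[["dx"]], 0.4)
  expect_equal(d[["dy"]], -0.3)
})

test_that("displacement estimation is robust to jitter and spurious spots", {
  f <- make_field(n_guide = 2000, jitter = 0.1, spurious = 0, seed = 10)
  d <- estimate_displacement(f$guide, f$bl6)
  expect_lt(abs(d[["dx"]] - 0.4), 0.02)
  expect_lt(abs(d[["dy"]] + 0.3), 0.02)

  # half the allele channel replaced by uniform spurious spots
  f2 <- make_field(n_guide = 1000, jitter = 0.1, p_b = 0.6, p_j = 0,
                   spurious = 0.6 * 1000 / 512^2, seed = 11)
  d2 <- estimate_displacement(f2$guide, f2$bl6)
  expect_lt(abs(d2[["dx"]] - 0.4), 0.05)
  expect_lt(abs(d2[["dy"]] + 0.3), 0.05)
})

test_that("too few matches raises an actionable error", {
  guide <- tibble::tibble(x = 1:20 * 10, y = 1:20 * 10)
  allele <- tibble::tibble(x = 1:20 * 10 + 5, y = 1:20 * 10)
  expect_error(estimate_displacement(guide, allele, window = 2.5),
               "enlarge the window")
})

test_that("single-pair geometry and dual matches are classified correctly", {
  guide <- tibble::tibble(x = 10, y = 10)
  bl6 <- tibble::tibble(x = 10.2, y = 10.1)
  jf1 <- tibble::tibble(x = numeric(), y = numeric())
  res <- colocalize_spots(guide, bl6, jf1, radius = 0.5)
  expect_equal(res$guides$assignment, "BL6")
  expect_equal(res$guides$bl6_dist, sqrt(0.05))

  jf1b <- tibble::tibble(x = 10.1, y = 9.9)
  both <- colocalize_spots(guide, bl6, jf1b, radius = 0.5)
  expect_equal(both$guides$assignment, "both")
  expect_equal(both$rates[["overall_coloc"]], 1)
  expect_equal(both$rates[["unique_coloc"]], 0)
})

test_that("unique assignments track ground truth on a realistic field", {
  f <- make_field(n_guide = 2000, seed = 12)
  d <- estimate_displacement(f$guide, f$bl6)
  res <- colocalize_spots(f$guide, f$bl6, f$jf1, radius = 0.8,
                          displacement = d)
  truth_frac <- mean(f$truth$true_assignment != "none")
  expect_lt(abs(res$rates[["unique_coloc"]] - truth_frac), 0.02)
  expect_gt(mean(res$guides$assignment == f$truth$true_assignment), 0.97)
})

test_that("greedy matching never reuses an allele spot", {
  f <- make_field(n_guide = 500, jitter = 0.3, spurious = 5e-4, seed = 13)
  res <- colocalize_spots(f$guide, f$bl6, f$jf1, radius = 1.5)
  expect_false(any(duplicated(stats::na.omit(res$guides$bl6_partner))))
  expect_false(any(duplicated(stats::na.omit(res$guides$jf1_partner))))
})

test_that("matching is invariant under joint translation of all channels", {
  f <- make_field(n_guide = 300, seed = 14)
  res <- colocalize_spots(f$guide, f$bl6, f$jf1, radius = 0.8)
  shift <- function(tb) dplyr::mutate(tb, x = x + 37.5, y = y - 12.25)
  res2 <- colocalize_spots(shift(f$guide), shift(f$bl6), shift(f$jf1),
                           radius = 0.8)
  expect_equal(res2$guides$assignment, res$guides$assignment)
  expect_equal(res2$rates, res$rates)
})

test_that("pixel-shift control removes genuine and keeps chance colocalization", {
  guide <- tibble::tibble(x = 50, y = 50)
  partner <- tibble::tibble(x = 50, y = 50)
  none <- tibble::tibble(x = numeric(), y = numeric())
  sh <- pixel_shift_null(guide, partner, none, radius = 0.5)
  expect_equal(sh$rates[["overall_coloc"]], 0)

  # spurious-only channels follow the Poisson-process chance rate
  # (1 - exp(-2 rho pi r^2) for two allele channels of density rho);
  # realized densities are used, and enough guides to tame Poisson noise
  rho <- 2e-3; r <- 1
  f <- gen_spot_field(spot_field_spec(
    image_extent = c(1000, 1000), n_guide = 20000, coloc_prob_bl6 = 0,
    coloc_prob_jf1 = 0, spurious_density = rho, rng_seed = 15))
  sh2 <- pixel_shift_null(f$guide, f$bl6, f$jf1, radius = r)
  expected <- 1 - exp(-(nrow(f$bl6) + nrow(f$jf1)) / 1e6 * pi * r^2)
  expect_lt(abs(sh2$rates[["overall_coloc"]] / expected - 1), 0.2)
})

test_that("shifted rates do not depend on the true colocalization probability", {
  rates <- vapply(c(0, 0.4), function(p) {
    f <- gen_spot_field(spot_field_spec(
      image_extent = c(1000, 1000), n_guide = 3000, coloc_prob_bl6 = p,
      coloc_prob_jf1 = 0, spurious_density = 2e-3, rng_seed = 16))
    pixel_shift_null(f$guide, f$bl6, f$jf1, radius = 1)$rates[["overall_coloc"]]
  }, numeric(1))
  expect_lt(abs(rates[1] - rates[2]), 0.03)
})

test_that("radius selection follows the objective with small-radius tie-break", {
  f <- gen_spot_field(spot_field_spec(
    n_guide = 200, coloc_prob_bl6 = 0.5, coloc_prob_jf1 = 0.5,
    localization_jitter_sd = 0, spurious_density = 0, rng_seed = 17))
  scan <- select_radius(f$guide, f$bl6, f$jf1, radii = c(0.5, 1, 1.5))
  expect_equal(scan$chosen_radius, 0.5)

  f2 <- make_field(n_guide = 2000, seed = 18)
  d <- estimate_displacement(f2$guide, f2$bl6)
  scan2 <- select_radius(f2$guide, f2$bl6, f2$jf1, displacement = d)
  obj <- scan2$scan$objective
  chosen_obj <- obj[scan2$scan$radius == scan2$chosen_radius]
  expect_gte(scan2$chosen_radius, 0.4)
  expect_lte(scan2$chosen_radius, 1.2)
  expect_gte(chosen_obj, obj[1])
  expect_gte(chosen_obj, obj[length(obj)])
})

test_that("an all-spurious field triggers the null-field warning", {
  f <- gen_spot_field(spot_field_spec(
    image_extent = c(600, 600), n_guide = 400, coloc_prob_bl6 = 0,
    coloc_prob_jf1 = 0, spurious_density = 3e-4, rng_seed = 19))
  expect_warning(select_radius(f$guide, f$bl6, f$jf1,
                               radii = seq(0.5, 2.5, by = 0.5)),
                 "indistinguishable")
})

test_that("per-cell aggregation counts assignments and recovers exact truth", {
  res <- structure(list(guides = tibble::tibble(
    guide_id = 1:4, x = 0, y = 0, z = 0, cell_id = 1L,
    assignment = c("BL6", "BL6", "JF1", "none"),
    bl6_partner = NA, bl6_dist = NA, jf1_partner = NA, jf1_dist = NA),
    rates = c(overall_coloc = 0.75, unique_coloc = 0.75),
    radius = 1, displacement = c(0, 0), n_guide = 4L),
    class = "coloc_result")
  pc <- per_cell_counts(res)
  expect_equal(pc$n_bl6, 2L)
  expect_equal(pc$n_jf1, 1L)
  expect_equal(pc$n_unassigned, 1L)
  expect_equal(pc$n_dual, 0L)

  # end-to-end: noiseless field reproduces per-cell truth exactly
  f <- gen_spot_field(spot_field_spec(
    n_guide = 300, coloc_prob_bl6 = 0.4, coloc_prob_jf1 = 0.4,
    localization_jitter_sd = 0, spurious_density = 0, rng_seed = 20))
  pc2 <- per_cell_counts(colocalize_spots(f$guide, f$bl6, f$jf1, 0.5))
  truth <- f$truth |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(n_bl6 = sum(true_assignment == "BL6"),
                     n_jf1 = sum(true_assignment == "JF1"))
  expect_equal(pc2$n_bl6, as.integer(truth$n_bl6))
  expect_equal(pc2$n_jf1, as.integer(truth$n_jf1))
})
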