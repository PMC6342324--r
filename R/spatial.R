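## Spatial heterogeneity of allelic choice: grid-variance metric, permutation
## and seeded-cluster null models, and seed-size matching.

## Accept a tissue layout or foci table; normalize to x, y, identity.
check_layout <- function(layout) {
  if (!is.data.frame(layout) || !all(c("x", "y") %in% names(layout))) {
    abort("`layout` must be a data frame with columns `x`, `y` and an identity column.")
  }
  if (!"identity" %in% names(layout)) {
    if ("assignment" %in% names(layout)) {
      layout$identity <- layout$assignment
    } else {
      abort("`layout` needs an `identity` (or `assignment`) column with values \"BL6\"/\"JF1\".")
    }
  }
  bad <- setdiff(unique(layout$identity), c("BL6", "JF1"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown identities in layout: %s.",
                  paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(layout)
}

## Rectangle index of each point for an rows x cols partition of the points'
## bounding box (points on the far edge fall in the last rectangle).
rect_index <- function(x, y, rows, cols) {
  cx <- pmin(cols, pmax(1L, ceiling((x - min(x)) / (diff(range(x)) / cols))))
  cy <- pmin(rows, pmax(1L, ceiling((y - min(y)) / (diff(range(y)) / rows))))
  cx[x == min(x)] <- 1L
  cy[y == min(y)] <- 1L
  as.integer((cy - 1L) * cols + cx)
}

## Sample variance of per-rectangle BL6 fractions for many identity vectors
## at once. `id_mat`: n x n_rep matrix of 0/1 BL6 indicators.
grid_variance_matrix <- function(rect, n_rect, id_mat) {
  m_k <- tabulate(rect, n_rect)
  sums <- rowsum(id_mat, rect, reorder = TRUE)
  frac <- sums / m_k[as.integer(rownames(sums))]
  n_occ <- nrow(frac)
  if (n_occ < 2) {
    abort("All foci fall in fewer than two rectangles; variance is undefined. Use a finer grid or more foci.")
  }
  mu <- colMeans(frac)
  colSums((frac - rep(mu, each = n_occ))^2) / (n_occ - 1)
}

#' Grid-variance metric of spatial allelic heterogeneity
#'
#' Tiles the bounding box of the foci into `grid` equal rectangles, computes
#' the BL6 fraction among foci in each occupied rectangle, and returns the
#' sample variance (n - 1 denominator) of those fractions. Empty rectangles
#' are excluded (their fraction is undefined).
#'
#' @param layout A data frame of foci with columns `x`, `y` and `identity`
#'   (or `assignment`) taking values `"BL6"`/`"JF1"`; e.g. from
#'   [gen_tissue_layout()] or [classify_by_kmeans()].
#' @param grid Grid dimensions: a single integer for a square grid, or
#'   `c(rows, cols)`.
#' @return A list of class `spatial_variance`: `grid`, `tiles` (tibble with
#'   `row`, `col`, `n_foci`, `frac_bl6` for occupied rectangles), `variance`
#'   and `n_occupied`.
#' @export
#' @examples
#' layout <- gen_tissue_layout(500, 0.5, seed_size = 4, rng_seed = 1)
#' grid_variance(layout, grid = 8)$variance
grid_variance <- function(layout, grid) {
  layout <- check_layout(layout)
  if (nrow(layout) < 1) abort("`layout` has no foci.")
  grid <- as.integer(rep_len(grid, 2))
  if (any(grid < 1)) abort("`grid` dimensions must be >= 1.")
  rows <- grid[1]; cols <- grid[2]
  rect <- rect_index(layout$x, layout$y, rows, cols)
  id01 <- as.numeric(layout$identity == "BL6")
  m_k <- tabulate(rect, rows * cols)
  occ_rect <- which(m_k > 0)
  if (length(occ_rect) < 2) {
    abort("All foci fall in fewer than two rectangles; variance is undefined. Use a finer grid or more foci.")
  }
  sums <- rowsum(id01, rect)
  frac <- as.numeric(sums) / m_k[occ_rect]
  tiles <- tibble::tibble(
    row = (occ_rect - 1L) %/% cols + 1L,
    col = (occ_rect - 1L) %% cols + 1L,
    n_foci = m_k[occ_rect],
    frac_bl6 = frac
  )
  structure(list(grid = c(rows = rows, cols = cols), tiles = tiles,
                 variance = var(frac), n_occupied = length(occ_rect)),
            class = "spatial_variance")
}

#' @export
print.spatial_variance <- function(x, ...) {
  cat(sprintf("<spatial_variance> %dx%d grid: variance %.5g over %d occupied rectangles\n",
              x$grid[1], x$grid[2], x$variance, x$n_occupied))
  invisible(x)
}

#' Permutation null distribution of the grid variance
#'
#' Repeatedly permutes allelic identities across the fixed foci positions and
#' recomputes the grid variance, giving the baseline spatial heterogeneity
#' expected under random (spatially unstructured) allelic choice.
#'
#' @inheritParams grid_variance
#' @param n_perm Number of random permutations (default 1000).
#' @param rng_seed Optional integer seed.
#' @return A tibble with columns `sim` and `variance`, with attributes
#'   `mean` and `sd`.
#' @export
permutation_null <- function(layout, grid, n_perm = 1000, rng_seed = NULL) {
  layout <- check_layout(layout)
  n_perm <- assert_count(n_perm, "n_perm")
  grid <- as.integer(rep_len(grid, 2))
  rect <- rect_index(layout$x, layout$y, grid[1], grid[2])
  id01 <- as.numeric(layout$identity == "BL6")
  with_seed(rng_seed, {
    id_mat <- vapply(seq_len(n_perm), function(i) sample(id01),
                     numeric(length(id01)))
    v <- grid_variance_matrix(rect, grid[1] * grid[2], id_mat)
    out <- tibble::tibble(sim = seq_len(n_perm), variance = v)
    attr(out, "mean") <- mean(v)
    attr(out, "sd") <- sd(v)
    out
  })
}

#' Seeded-cluster null distributions of the grid variance
#'
#' For each seed size, regenerates allelic identities on the observed foci
#' positions by randomly seeding spatial clusters of that size (the
#' clustering rule of [gen_tissue_layout()]) while preserving the observed
#' allelic ratio, and recomputes the grid variance for every simulation and
#' every grid. Each simulated identity vector is shared across grids (the
#' positions are fixed, so the grid only re-bins the same simulation).
#'
#' @inheritParams grid_variance
#' @param grids Integer vector of square grid sizes (e.g. `c(4, 8, 16)` for
#'   4x4, 8x8 and 16x16).
#' @param seed_sizes Cluster sizes to simulate (default 1:10).
#' @param n_sim Simulations per seed size (default 500).
#' @param rng_seed Optional integer seed.
#' @return A tibble with columns `grid`, `seed_size`, `sim`, `variance`.
#' @export
seeded_cluster_null <- function(layout, grids, seed_sizes = 1:10,
                                n_sim = 500, rng_seed = NULL) {
  layout <- check_layout(layout)
  n_sim <- assert_count(n_sim, "n_sim")
  grids <- as.integer(grids)
  n <- nrow(layout)
  n_bl6 <- sum(layout$identity == "BL6")
  rects <- lapply(grids, function(g) rect_index(layout$x, layout$y, g, g))
  with_seed(rng_seed, {
    purrr::map_dfr(seed_sizes, function(s) {
      id_mat <- vapply(seq_len(n_sim), function(i) {
        as.numeric(reseed_identities(layout$x, layout$y, s, n_bl6) == "BL6")
      }, numeric(n))
      purrr::map_dfr(seq_along(grids), function(gi) {
        v <- grid_variance_matrix(rects[[gi]], grids[gi]^2, id_mat)
        tibble::tibble(grid = grids[gi], seed_size = s,
                       sim = seq_len(n_sim), variance = v)
      })
    })
  })
}

#' Match observed grid variances to the closest seeded-cluster null
#'
#' For every grid, selects the seed size whose mean simulated variance
#' deviates least from the observed variance (ties broken toward the smaller
#' seed), then summarises as the mean and standard deviation of the per-grid
#' best seeds.
#'
#' @param observed A tibble with columns `grid` and `variance` (observed grid
#'   variances, one row per grid).
#' @param nulls Output of [seeded_cluster_null()].
#' @return An object of class `seed_match`: `per_grid` tibble (`grid`,
#'   `observed_variance`, `best_seed`), `null_means` tibble (`grid`,
#'   `seed_size`, `mean_variance`, `sd_variance`), `mean_seed`, `sd_seed`.
#' @export
match_seed_size <- function(observed, nulls) {
  if (nrow(observed) < 2) {
    abort("`observed` must cover at least two grids.")
  }
  null_means <- nulls |>
    dplyr::group_by(.data$grid, .data$seed_size) |>
    dplyr::summarise(mean_variance = mean(.data$variance),
                     sd_variance = sd(.data$variance), .groups = "drop")
  per_grid <- observed |>
    dplyr::inner_join(null_means, by = "grid") |>
    dplyr::mutate(dev = abs(.data$variance - .data$mean_variance)) |>
    dplyr::group_by(.data$grid) |>
    dplyr::arrange(.data$dev, .data$seed_size, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(grid = .data$grid,
                     observed_variance = .data$variance,
                     best_seed = .data$seed_size)
  structure(list(per_grid = per_grid, null_means = null_means,
                 mean_seed = mean(per_grid$best_seed),
                 sd_seed = sd(per_grid$best_seed)),
            class = "seed_match")
}

#' @export
print.seed_match <- function(x, ...) {
  cat(sprintf("<seed_match> mean seed size %.2f (sd %.2f) across %d grids\n",
              x$mean_seed, x$sd_seed, nrow(x$per_grid)))
  print(x$per_grid)
  invisible(x)
}

#' Estimate the minimal cluster size of identical X-inactivation choice
#'
#' End-to-end wrapper: computes the observed grid variance over a range of
#' square grids, simulates seeded-cluster nulls for a range of seed sizes at
#' the observed allelic ratio, and matches the observed variance to the
#' closest null per grid. Optionally also computes the permutation null.
#'
#' @inheritParams seeded_cluster_null
#' @param n_perm Permutations for the baseline null (0 to skip).
#' @return A `seed_match` object, with extra elements `observed` (per-grid
#'   variances) and `permutation` (per-grid permutation-null tibble, if
#'   requested).
#' @export
#' @examples
#' layout <- gen_tissue_layout(1000, 0.5, seed_size = 4, rng_seed = 1)
#' est <- estimate_seed_size(layout, grids = c(4, 8), n_sim = 50, n_perm = 0,
#'                           rng_seed = 2)
#' est$mean_seed
estimate_seed_size <- function(layout, grids = 4:16,
                               seed_sizes = 1:10, n_sim = 500,
                               n_perm = 1000, rng_seed = NULL) {
  layout <- check_layout(layout)
  observed <- purrr::map_dfr(grids, function(g) {
    tibble::tibble(grid = as.integer(g),
                   variance = grid_variance(layout, g)$variance)
  })
  nulls <- seeded_cluster_null(layout, grids, seed_sizes, n_sim,
                               rng_seed = child_seed(rng_seed, 1))
  res <- match_seed_size(observed, nulls)
  res$observed <- observed
  if (n_perm > 0) {
    res$permutation <- purrr::map_dfr(seq_along(grids), function(gi) {
      pn <- permutation_null(layout, grids[gi], n_perm,
                             rng_seed = child_seed(rng_seed, 100 + gi))
      tibble::tibble(grid = as.integer(grids[gi]), sim = pn$sim,
                     variance = pn$variance)
    })
  }
  res
}
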