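#' Generate a spatially clustered tissue layout of allelic identities
#'
#' Places `n_cells` uniformly in a rectangular field and partitions them into
#' spatial clusters of `seed_size` cells by repeatedly picking a random
#' unassigned cell together with its `seed_size - 1` nearest unassigned
#' neighbours. Whole clusters are then labelled BL6 or JF1 by shuffling a
#' quota of `round(n_clusters * p_bl6)` BL6 labels, so the population allelic
#' ratio is preserved up to cluster granularity; any residual imbalance is
#' corrected by flipping one randomly chosen cluster when an exact correction
#' exists.
#'
#' @param n_cells Number of cells (>= `seed_size`).
#' @param p_bl6 Target BL6 fraction in `[0, 1]`.
#' @param seed_size Cells per cluster of identical X-inactivation choice
#'   (integer >= 1; `1` reduces to a random permutation of labels).
#' @param extent Field size `c(width, height)` in pixels.
#' @param rng_seed Optional integer seed.
#' @return A tibble with columns `x`, `y`, `cluster` and `identity`
#'   ("BL6"/"JF1"), with attributes `seed_size` and `extent`.
#' @export
#' @examples
#' layout <- gen_tissue_layout(200, p_bl6 = 0.5, seed_size = 4, rng_seed = 1)
#' table(layout$identity)
gen_tissue_layout <- function(n_cells, p_bl6, seed_size,
                              extent = c(1000, 1000), rng_seed = NULL) {
  n_cells <- assert_count(n_cells, "n_cells")
  seed_size <- assert_count(seed_size, "seed_size")
  assert_prob(p_bl6, "p_bl6")
  if (n_cells < seed_size) {
    abort("`n_cells` must be at least `seed_size`.",
          class = "allelefish_config_error")
  }
  with_seed(rng_seed, {
    x <- runif(n_cells, 0, extent[1])
    y <- runif(n_cells, 0, extent[2])
    cluster <- cpp_seed_clusters(x, y, seed_size, sample.int(n_cells))
    identity <- assign_cluster_identities(cluster, p_bl6)
    out <- tibble::tibble(x = x, y = y, cluster = cluster,
                          identity = identity)
    attr(out, "seed_size") <- seed_size
    attr(out, "extent") <- extent
    out
  })
}

## Label whole clusters BL6/JF1 at quota round(K * p_bl6); flip one randomly
## chosen cluster afterwards if that exactly removes residual imbalance
## (possible when cluster sizes are unequal).
assign_cluster_identities <- function(cluster, p_bl6) {
  sizes <- tabulate(cluster)
  k <- length(sizes)
  n <- length(cluster)
  n_bl6_clusters <- round(k * p_bl6)
  labels <- sample(rep(c("BL6", "JF1"),
                       c(n_bl6_clusters, k - n_bl6_clusters)))
  realized <- sum(sizes[labels == "BL6"])
  target <- round(n * p_bl6)
  diff <- realized - target
  if (diff != 0) {
    flip_from <- if (diff > 0) "BL6" else "JF1"
    candidates <- which(labels == flip_from & sizes == abs(diff))
    if (length(candidates) > 0) {
      pick <- candidates[sample.int(length(candidates), 1)]
      labels[pick] <- setdiff(c("BL6", "JF1"), flip_from)
    }
  }
  labels[cluster]
}

## Regenerate identities on fixed positions with a fixed BL6 *count*,
## clustering at `seed_size`. Used by the seeded-cluster null, where the
## observed allelic ratio must be preserved in every simulation.
reseed_identities <- function(x, y, seed_size, n_bl6) {
  n <- length(x)
  cluster <- cpp_seed_clusters(x, y, seed_size, sample.int(n))
  assign_cluster_identities(cluster, n_bl6 / n)
}
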