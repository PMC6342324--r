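## Internal helpers: argument validation, reproducible RNG scoping, shared
## table constructors.

assert_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 ||
      (!allow_zero && x == 0) || (!allow_one && x == 1)) {
    abort(sprintf("`%s` must be a single probability in %s%s, %s%s.",
                  name,
                  if (allow_zero) "[" else "(", "0",
                  "1", if (allow_one) "]" else ")"),
          class = "allelefish_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "allelefish_config_error")
  }
  invisible(as.integer(x))
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "allelefish_config_error")
  }
  invisible(x)
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. `seed = NULL` leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Deterministic child stream k of a root seed (kept below 2^31 so it is a
## valid R integer seed). Used by multi-stage operations so partial reruns
## reproduce.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629) + 1L
}

## Canonical per-cell allelic count table.
new_allele_counts <- function(n_bl6, n_jf1, n_unassigned = 0L, n_dual = 0L,
                              total = NULL, cell_id = seq_along(n_bl6)) {
  out <- tibble::tibble(
    cell_id = as.integer(cell_id),
    n_bl6 = as.integer(n_bl6),
    n_jf1 = as.integer(n_jf1),
    n_unassigned = as.integer(rep_len(n_unassigned, length(n_bl6))),
    n_dual = as.integer(rep_len(n_dual, length(n_bl6)))
  )
  if (!is.null(total)) out$total <- as.integer(total)
  out
}

## Validate (and lightly coerce) a user-supplied count table.
check_allele_counts <- function(counts, require_total = FALSE) {
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame with columns `n_bl6` and `n_jf1`.")
  }
  for (col in c("n_bl6", "n_jf1")) {
    if (!col %in% names(counts)) {
      abort(sprintf("`counts` is missing required column `%s`.", col))
    }
    if (any(counts[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("`counts$%s` contains negative values.", col))
    }
  }
  if (require_total) {
    if (!"total" %in% names(counts)) {
      abort("`counts` must carry a `total` column for this analysis.")
    }
    if (any(counts$total < counts$n_bl6 + counts$n_jf1)) {
      abort("`total` must be >= n_bl6 + n_jf1 in every cell.")
    }
  }
  if (!"cell_id" %in% names(counts)) {
    counts <- dplyr::mutate(counts, cell_id = dplyr::row_number())
  }
  tibble::as_tibble(counts)
}

## Two-sided empirical p-value with add-one smoothing: never 0, never > 1.
## NA/NaN null draws (e.g. a degenerate correlation) are dropped.
empirical_p_value <- function(observed, null) {
  null <- null[!is.na(null)]
  n <- length(null)
  p_le <- (sum(null <= observed) + 1) / (n + 1)
  p_ge <- (sum(null >= observed) + 1) / (n + 1)
  min(1, 2 * min(p_le, p_ge))
}

empirical_percentile <- function(observed, null) {
  null <- null[!is.na(null)]
  100 * sum(null <= observed) / length(null)
}
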