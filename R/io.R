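## Plain-text and TIFF input/output for the pipeline's tables and images.

#' Read and write per-cell allelic count tables
#'
#' Tab-separated tables with columns `cell_id`, `n_bl6`, `n_jf1`,
#' `n_unassigned`, `n_dual` and optionally `total`.
#'
#' @param counts A per-cell count table.
#' @param path File path.
#' @return `read_allele_counts()` returns a validated tibble;
#'   `write_allele_counts()` returns `path` invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  readr::write_tsv(check_allele_counts(counts), path)
  invisible(path)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  check_allele_counts(readr::read_tsv(path, show_col_types = FALSE))
}

#' Read and write spot tables
#'
#' Tab-separated tables with columns `channel`, `x`, `y`, `z`, `intensity`,
#' `cell_id`.
#'
#' @param spots A spot table.
#' @param path File path.
#' @return `read_spot_table()` returns a tibble; `write_spot_table()`
#'   returns `path` invisibly.
#' @export
write_spot_table <- function(spots, path) {
  readr::write_tsv(check_spot_table(spots, "spots"), path)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  check_spot_table(readr::read_tsv(path, show_col_types = FALSE), "spots")
}

#' Read and write 16-bit grayscale TIFF images
#'
#' Images are stored as 16-bit grayscale TIFF; in memory they are plain
#' numeric matrices (first index x) on the original intensity scale.
#'
#' @param image A numeric matrix with values in `[0, 65535]`.
#' @param path File path.
#' @return `read_image_tiff()` returns a numeric matrix;
#'   `write_image_tiff()` returns `path` invisibly.
#' @export
write_image_tiff <- function(image, path) {
  scaled <- pmin(pmax(image / 65535, 0), 1)
  EBImage::writeImage(EBImage::Image(scaled), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  EBImage::imageData(EBImage::readImage(path)) * 65535
}
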