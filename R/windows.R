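#' Define a non-overlapping window grid over a target region
#'
#' Windows tile the region `[region_start, region_end]` (1-based, inclusive)
#' left to right; the last window may be shorter than `window_size`.
#'
#' @param chrom Chromosome (reference sequence) name.
#' @param region_start,region_end 1-based inclusive region bounds.
#' @param window_size Window width in bp (default 500, minimum 50).
#' @return An object of class `window_grid`: a list with `chrom`,
#'   `region_start`, `region_end`, `window_size`, and per-window `starts`,
#'   `ends` and count `n`.
#' @examples
#' g <- window_grid("chr1", 1, 1200, 500)
#' g$ends  # 500 1000 1200
#' @export
window_grid <- function(chrom, region_start, region_end, window_size = 500) {
  stopifnot(length(chrom) == 1L, length(region_start) == 1L,
            length(region_end) == 1L)
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  window_size <- as.integer(window_size)
  if (region_end <= region_start)
    stop("region_end must be greater than region_start")
  if (window_size < 50L)
    stop("window_size must be at least 50 bp")
  starts <- seq.int(region_start, region_end, by = window_size)
  ends <- pmin(starts + window_size - 1L, region_end)
  structure(
    list(chrom = as.character(chrom), region_start = region_start,
         region_end = region_end, window_size = window_size,
         starts = starts, ends = ends, n = length(starts)),
    class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %s:%d-%d, %d windows of %d bp\n",
              x$chrom, x$region_start, x$region_end, x$n, x$window_size))
  invisible(x)
}

# Window index of each 1-based position; NA outside the region.
window_index <- function(grid, pos) {
  idx <- (as.numeric(pos) - grid$region_start) %/% grid$window_size + 1
  idx[pos < grid$region_start | pos > grid$region_end] <- NA_integer_
  as.integer(idx)
}

# Labels like "chr1:1-500" used in exported matrices.
window_labels <- function(grid) {
  sprintf("%s:%d-%d", grid$chrom, grid$starts, grid$ends)
}
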