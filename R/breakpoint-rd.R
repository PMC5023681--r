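## Read-depth stage of breakpoint estimation: Gaussian-kernel scoring of
## sub-region boundaries and bootstrap medians (MedLeft / MedRight).

#' Zero-pad a group's sub-matrix with flanking sub-regions
#'
#' Appends one flanking sub-region on each side of the CNVR with
#' segmentation value 0 for every sample, reflecting the assumption that
#' the CNVR's neighbourhood is copy-neutral. The boundary positions between
#' consecutive padded columns (CNVR edges included) become the candidate
#' breakpoint positions. Padding is not idempotent: padding twice adds two
#' flanks.
#'
#' @param v Numeric matrix, group samples x N CNVR sub-regions.
#' @param boundaries The N+1 sub-region boundary coordinates in bp (each
#'   the start of the sub-region to its right; the last is one past the
#'   CNVR end).
#' @return List with `values` (samples x N+2 padded matrix) and
#'   `positions` (the N+1 candidate junction coordinates, identical to
#'   `boundaries`).
#' @export
pad_group_matrix <- function(v, boundaries) {
  v <- as.matrix(v)
  if (nrow(v) == 0 || ncol(v) == 0) stop("group sub-matrix is empty")
  if (length(boundaries) != ncol(v) + 1L)
    stop("need ncol(v) + 1 boundary positions")
  zeros <- matrix(0, nrow(v), 1)
  list(values = cbind(zeros, v, zeros), positions = as.numeric(boundaries))
}

#' Gaussian-kernel read-depth score for candidate breakpoint positions
#'
#' For each candidate position `mu_j`, sums over samples and over boundary
#' positions `x_k` the product of the sample's boundary weight and a normal
#' density centred at the candidate:
#' `score(P_j) = sum_i sum_k w_k(i) * dnorm(x_k, mu_j, sigma)`, where
#' `w_k(i)` is the absolute difference between the sample's segmentation
#' values in the two sub-regions flanking `x_k`. Positions adjacent to true
#' copy-number steps in many samples score highest.
#'
#' @param padded A [pad_group_matrix()] result (or any list with `values`
#'   and `positions`).
#' @param sigma Kernel standard deviation in bp (default: one third of the
#'   window size at the usual operating point).
#' @param candidates Positions at which to evaluate the score (default:
#'   the boundary positions themselves).
#' @return Numeric vector of non-negative scores, one per candidate.
#' @export
rd_scores <- function(padded, sigma, candidates = padded$positions) {
  v <- padded$values
  x <- padded$positions
  stopifnot(sigma > 0, length(x) == ncol(v) - 1L)
  w <- colSums(abs(v[, -1, drop = FALSE] - v[, -ncol(v), drop = FALSE]))
  k <- stats::dnorm(outer(x, candidates, "-"), sd = sigma)
  as.vector(crossprod(k, w))
}

# Indices of the two top-scoring positions; ties broken toward the
# smallest coordinate.
top2_positions <- function(scores, positions) {
  ord <- order(-scores, positions)
  sort(positions[ord[1:2]])
}

#' Bootstrap breakpoint estimation from read depth
#'
#' Resamples the group's samples with replacement `n_resample` times; each
#' replicate's two top-scoring candidate positions are recorded (smaller
#' coordinate = left). `MedLeft`/`MedRight` are the medians of the
#' replicate left and right positions.
#'
#' @inheritParams rd_scores
#' @param n_resample Number of bootstrap replicates (default 100).
#' @return An object of class `rd_breakpoints`: list with `med_left`,
#'   `med_right`, `score_profile` (full-group scores per candidate),
#'   `positions`, and `pairs` (n_resample x 2 matrix of replicate pairs).
#' @export
bootstrap_breakpoints <- function(padded, sigma, n_resample = 100,
                                  candidates = padded$positions) {
  if (length(candidates) < 2)
    stop("need at least 2 distinct candidate positions to bracket an event")
  v <- padded$values
  x <- padded$positions
  wmat <- abs(v[, -1, drop = FALSE] - v[, -ncol(v), drop = FALSE])
  k <- stats::dnorm(outer(x, candidates, "-"), sd = sigma)
  m <- nrow(v)
  pairs <- t(vapply(seq_len(n_resample), function(r) {
    idx <- sample.int(m, m, replace = TRUE)
    w <- colSums(wmat[idx, , drop = FALSE])
    top2_positions(as.vector(crossprod(k, w)), candidates)
  }, numeric(2)))
  profile <- as.vector(crossprod(k, colSums(wmat)))
  structure(list(med_left = stats::median(pairs[, 1]),
                 med_right = stats::median(pairs[, 2]),
                 score_profile = profile, positions = candidates,
                 pairs = pairs),
            class = "rd_breakpoints")
}

#' @export
print.rd_breakpoints <- function(x, ...) {
  cat(sprintf("<rd_breakpoints> MedLeft = %s, MedRight = %s (%d replicates)\n",
              format(x$med_left), format(x$med_right), nrow(x$pairs)))
  invisible(x)
}
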