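## Per-sample segmentation, the shared sub-region partition, and CNVR calls.

#' Segment one sample's standardized signal into constant pieces
#'
#' Least-squares segmentation in the style of circular binary
#' segmentation: each scan of a segment considers both the best single
#' split and the best interior sub-segment (a pair of change-points tested
#' jointly, which is what makes short events detectable inside long flat
#' stretches), and accepts the alternative whose sum-of-squares reduction
#' most exceeds its penalty; accepted change-points are recursed on. The
#' penalties are Bonferroni/SIC-style, `2 sigma^2 log(n)` for a single
#' split and `2 sigma^2 log(n (n-1) / 2)` for an interior pair (matching
#' the number of candidates scanned). Paired-end read starts are serially
#' correlated over the mate-pair span (roughly one window), which both
#' inflates the variance of segment means and makes lag-1 differences
#' understate the marginal noise. The marginal variance is therefore
#' estimated from lag-3 differences (which straddle the mate correlation
#' yet still cancel the piecewise mean structure), short-lag
#' autocorrelations are estimated from the lag-1/lag-2 difference MADs,
#' and each candidate's gain is deflated by the moving-average variance
#' inflation factor `1 + 2 rho1 (1 - 1/m) + 2 rho2 (1 - 2/m)` of its
#' shorter side before the penalty comparison. For single-end data the
#' estimated correlations are near zero and the scan reduces to the iid
#' case.
#'
#' @param x Numeric signal, one value per window.
#' @param penalty Optional single-split penalty override (sum-of-squares
#'   scale); the pair penalty scales with it.
#' @return An object of class `segmentation`: list with `changepoints`
#'   (1-based indices of each right-hand segment's first window, possibly
#'   empty), `means` (one per segment) and `fitted` (per-window).
#' @examples
#' s <- segment_sample(c(rep(0, 5), rep(-1, 5)))
#' s$changepoints  # 6
#' @export
segment_sample <- function(x, penalty = NULL) {
  x <- as.numeric(x)
  if (length(x) == 0 || all(is.na(x))) stop("signal is empty or all-missing")
  if (anyNA(x)) stop("signal contains missing values")
  n <- length(x)
  rho1 <- rho2 <- 0
  sigma2 <- if (is.null(penalty)) {
    lag <- min(3L, n - 1L)
    s2 <- max((stats::mad(diff(x, lag = lag)) / sqrt(2))^2, 0)
    if (s2 > 0 && n > 6) {
      d1 <- (stats::mad(diff(x, lag = 1)) / sqrt(2))^2
      d2 <- (stats::mad(diff(x, lag = 2)) / sqrt(2))^2
      rho1 <- min(max(1 - d1 / s2, 0), 0.8)
      rho2 <- min(max(1 - d2 / s2, 0), 0.8)
    }
    s2
  } else penalty / (2 * log(max(n, 2)))
  # variance inflation of an m-window mean under MA(2)-type correlation
  vif <- function(m) pmax(1, 1 + 2 * rho1 * (1 - 1 / m) +
                             2 * rho2 * pmax(1 - 2 / m, 0))
  cps <- integer(0)
  if (n >= 2) {
    S <- c(0, cumsum(x))
    # Scan x[lo..hi]: best single split and best interior segment, each
    # judged against its own multiplicity-matched penalty.
    scan_segment <- function(lo, hi) {
      nn <- hi - lo + 1L
      pen1 <- max(2 * sigma2 * log(nn), 1e-10)
      tot <- S[hi + 1] - S[lo]
      j <- lo:(hi - 1)
      sl <- S[j + 1] - S[lo]
      g1 <- (sl^2 / (j - lo + 1) + (tot - sl)^2 / (hi - j) - tot^2 / nn) /
        vif(pmin(j - lo + 1, hi - j))
      k <- which.max(g1)
      best <- list(excess = g1[k] - pen1, cps = j[k] + 1L)
      if (nn >= 4) {
        pen2 <- max(2 * sigma2 * log(nn * (nn - 1) / 2), 1e-10)
        for (m in 1:(nn - 2)) {          # interior segment length
          a <- (lo + 1L):(hi - m)        # segment start; end = a + m - 1
          sin_ <- S[a + m] - S[a]
          g2 <- (sin_^2 / m + (tot - sin_)^2 / (nn - m) - tot^2 / nn) /
            vif(min(m, nn - m))
          k <- which.max(g2)
          if (g2[k] - pen2 > best$excess)
            best <- list(excess = g2[k] - pen2,
                         cps = c(a[k], a[k] + m))
        }
      }
      best
    }
    stack <- list(c(1L, n))
    while (length(stack)) {
      seg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (seg[2] - seg[1] < 1L) next
      bs <- scan_segment(seg[1], seg[2])
      if (bs$excess > 0) {
        cps <- c(cps, bs$cps)
        bounds <- c(seg[1], bs$cps, seg[2] + 1L)
        for (p in seq_len(length(bounds) - 1L))
          stack <- c(stack, list(c(bounds[p], bounds[p + 1] - 1L)))
      }
    }
    cps <- sort(unique(cps))
  }
  bounds <- c(1L, cps, n + 1L)
  means <- vapply(seq_len(length(bounds) - 1L), function(k)
    mean(x[bounds[k]:(bounds[k + 1] - 1L)]), numeric(1))
  fitted <- rep(means, diff(bounds))
  structure(list(changepoints = cps, means = means, fitted = fitted),
            class = "segmentation")
}

#' Build the shared sub-region partition from all samples' change-points
#'
#' Boundaries are the deduplicated, sorted union of every sample's
#' change-point coordinates (the 1-based start of each right-hand segment's
#' first window) plus the region ends; consecutive boundaries delimit the
#' non-overlapping sub-regions on which all samples' segmentations are
#' jointly piecewise-constant.
#'
#' @param segs List of `segmentation` objects (window-index space).
#' @param grid The [window_grid()] the signals were computed on.
#' @return An object of class `subregion_partition`: list with `boundaries`
#'   (bp; length N+1) and `sub_regions` (data frame `start`, `end`,
#'   1-based inclusive; N rows).
#' @export
build_partition <- function(segs, grid) {
  if (length(segs) == 0) stop("at least one segmentation is required")
  cp_idx <- sort(unique(unlist(lapply(segs, `[[`, "changepoints"))))
  bp <- grid$starts[cp_idx]
  boundaries <- sort(unique(c(grid$region_start, bp, grid$region_end + 1L)))
  sub_regions <- data.frame(
    start = boundaries[-length(boundaries)],
    end = boundaries[-1] - 1L)
  structure(list(boundaries = boundaries, sub_regions = sub_regions,
                 chrom = grid$chrom),
            class = "subregion_partition")
}

#' @export
print.subregion_partition <- function(x, ...) {
  cat(sprintf("<subregion_partition> %d sub-regions over %s:%d-%d\n",
              nrow(x$sub_regions), x$chrom, x$sub_regions$start[1],
              x$sub_regions$end[nrow(x$sub_regions)]))
  invisible(x)
}

#' Evaluate all samples' segmentations on the shared sub-regions
#'
#' @param segs List of `segmentation` objects, one per sample.
#' @param partition A [build_partition()] result whose boundaries contain
#'   every sample's change-points (so each fit is constant per sub-region).
#' @param grid The common [window_grid()].
#' @param sample_ids Row labels.
#' @return An object of class `seg_matrix`: list with `values` (M samples x
#'   N sub-regions), `partition` and `sample_ids`.
#' @export
seg_matrix <- function(segs, partition, grid,
                       sample_ids = names(segs)) {
  widx <- window_index(grid, partition$sub_regions$start)
  values <- matrix(unlist(lapply(segs, function(s) s$fitted[widx])),
                   nrow = length(segs), ncol = length(widx), byrow = TRUE)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(segs))
  rownames(values) <- sample_ids
  structure(list(values = values, partition = partition,
                 sample_ids = sample_ids),
            class = "seg_matrix")
}

#' Call copy-number-variable regions from the segmentation-value matrix
#'
#' Per sample and sub-region, the state is `DUP` if the segmentation value
#' exceeds `dup_threshold`, `DEL` if below `del_threshold`, else `NORMAL`.
#' Consecutive sub-regions in which any sample is non-normal are merged
#' into one CNVR; CNVRs carried by fewer than `count_threshold` samples are
#' dropped.
#'
#' @param sm A [seg_matrix()].
#' @param dup_threshold,del_threshold Standardized-depth thresholds
#'   (defaults +0.25 / -0.25; must bracket 0).
#' @param count_threshold Minimum carrier count (default 1; for population
#'   data a value near 10 percent of the sample size is recommended so only
#'   common events are reported).
#' @return An object of class `cnvr_calls`: list with `cnvrs` (data frame
#'   `cnvr_id`, `start`, `end`, `first_sub`, `last_sub`, `carrier_count`),
#'   the per-sample `states` matrix, and the input `seg`.
#' @export
call_cnvrs <- function(sm, dup_threshold = 0.25, del_threshold = -0.25,
                       count_threshold = 1) {
  stopifnot(inherits(sm, "seg_matrix"))
  if (!(del_threshold < 0 && 0 < dup_threshold))
    stop("thresholds must satisfy del_threshold < 0 < dup_threshold")
  v <- sm$values
  states <- matrix("NORMAL", nrow(v), ncol(v),
                   dimnames = list(sm$sample_ids, NULL))
  states[v > dup_threshold] <- "DUP"
  states[v < del_threshold] <- "DEL"
  variant <- apply(states != "NORMAL", 2, any)
  r <- rle(variant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    sub <- starts[k]:ends[k]
    carriers <- apply(states[, sub, drop = FALSE] != "NORMAL", 1, any)
    data.frame(first_sub = starts[k], last_sub = ends[k],
               carrier_count = sum(carriers))
  })
  cnvrs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(first_sub = integer(), last_sub = integer(),
                           carrier_count = integer())
  cnvrs <- cnvrs[cnvrs$carrier_count >= count_threshold, , drop = FALSE]
  sr <- sm$partition$sub_regions
  cnvrs <- data.frame(
    cnvr_id = seq_len(nrow(cnvrs)),
    start = sr$start[cnvrs$first_sub], end = sr$end[cnvrs$last_sub],
    first_sub = cnvrs$first_sub, last_sub = cnvrs$last_sub,
    carrier_count = cnvrs$carrier_count, row.names = NULL)
  structure(list(cnvrs = cnvrs, states = states, seg = sm),
            class = "cnvr_calls")
}

#' @export
print.cnvr_calls <- function(x, ...) {
  cat(sprintf("<cnvr_calls> %d CNVR(s) across %d samples\n",
              nrow(x$cnvrs), nrow(x$states)))
  if (nrow(x$cnvrs)) print(x$cnvrs[c("cnvr_id", "start", "end",
                                     "carrier_count")], row.names = FALSE)
  invisible(x)
}
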