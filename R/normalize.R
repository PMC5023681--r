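## Bias correction and standardization of windowed read counts.

#' Correct raw window counts for GC (and mappability) bias
#'
#' Median-ratio correction in annotation bins: the count of window *i* is
#' scaled by `m / m_bin(i)`, where `m` is the sample's overall median count
#' and `m_bin(i)` the median count of all windows falling in the same GC
#' (then, in `"gc+mappability"` mode, the same transform over mappability)
#' bin. Windows with missing annotation, an empty/zero-median bin, or a
#' bin holding fewer than `min_bin` windows pass through unchanged and are
#' flagged: a bin median estimated from a handful of windows is dominated
#' by those windows' own copy-number signal (in the extreme, a singleton
#' bin is forced to the sample median, erasing its signal entirely).
#'
#' @param raw A `raw_counts` object with its `gc_fraction` (and, for the
#'   combined mode, `mappability`) fields filled in, e.g. from
#'   [compute_gc_track()].
#' @param mode `"gc"` (default) or `"gc+mappability"`.
#' @param bin_width Annotation bin width (default 0.01).
#' @param min_bin Minimum windows per bin for the bin median to be used
#'   (default 10).
#' @return The `raw_counts` object with numeric corrected `counts` and a
#'   logical `uncorrected` field marking pass-through windows.
#' @export
bias_correct <- function(raw, mode = c("gc", "gc+mappability"),
                         bin_width = 0.01, min_bin = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(raw, "raw_counts"))
  if (is.null(raw$gc_fraction))
    stop("gc_fraction annotation is required for bias correction")
  if (all(raw$counts == 0))
    stop("sample ", raw$sample_id,
         " has all-zero counts; cannot form bin medians")
  x <- as.numeric(raw$counts)
  flagged <- logical(length(x))
  res <- median_ratio_correct(x, raw$gc_fraction, bin_width, min_bin)
  x <- res$x; flagged <- flagged | res$flagged
  if (mode == "gc+mappability") {
    if (is.null(raw$mappability))
      stop("mappability annotation is required for gc+mappability mode")
    res <- median_ratio_correct(x, raw$mappability, bin_width, min_bin)
    x <- res$x; flagged <- flagged | res$flagged
  }
  raw$counts <- x
  raw$uncorrected <- flagged
  raw
}

median_ratio_correct <- function(x, ann, bin_width, min_bin = 1) {
  ok <- !is.na(ann)
  m <- stats::median(x)
  bins <- floor(ann / bin_width)
  out <- x
  flagged <- !ok
  for (b in unique(bins[ok])) {
    sel <- ok & bins == b
    mb <- stats::median(x[sel])
    if (sum(sel) < min_bin || is.na(mb) || mb <= 0) {
      flagged[sel] <- TRUE
    } else {
      out[sel] <- x[sel] * m / mb
    }
  }
  list(x = out, flagged = flagged)
}

#' Standardize a counts matrix to a depth-free scale
#'
#' The default `"median_window"` method divides each sample's window counts
#' by that sample's median count across windows and subtracts 1, so 0
#' corresponds to the diploid state, -0.5 to a hemizygous deletion and -1
#' to a homozygous deletion. The `"cnvrd2"` alternative z-standardizes each
#' sample across windows and then each window across samples; it assumes
#' variant windows are a minority of the region (a warning restates this),
#' since otherwise variant copy numbers are pulled toward the apparent
#' normal.
#'
#' @param counts Samples x windows numeric matrix (or a single sample's
#'   vector), raw or bias-corrected.
#' @param method `"median_window"` (default) or `"cnvrd2"`.
#' @return Numeric matrix of the same shape (vectors are returned as 1-row
#'   matrices), samples x windows, on the standardized scale.
#' @export
standardize <- function(counts, method = c("median_window", "cnvrd2")) {
  method <- match.arg(method)
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = 1,
                     dimnames = list(NULL, names(counts)))
  counts <- as.matrix(counts)
  if (method == "median_window") {
    med <- apply(counts, 1, stats::median)
    bad <- med <= 0 | !is.finite(med)
    if (any(bad))
      stop("zero or undefined median read count for sample(s): ",
           paste(if (!is.null(rownames(counts))) rownames(counts)[bad]
                 else which(bad), collapse = ", "))
    sweep(counts, 1, med, "/") - 1
  } else {
    warning("cnvrd2 standardization assumes duplicated/deleted windows ",
            "are a minority of the region; variant regions that dominate ",
            "the region can be pushed toward the apparent diploid level")
    z <- t(apply(counts, 1, function(r) {
      s <- stats::sd(r)
      if (!is.finite(s) || s == 0) stop("constant sample signal cannot be ",
                                        "z-standardized")
      (r - mean(r)) / s
    }))
    apply(z, 2, function(cl) {
      s <- stats::sd(cl)
      if (!is.finite(s) || s == 0) cl - mean(cl) else (cl - mean(cl)) / s
    })
  }
}
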