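## Copy-number genotype grouping within a CNVR.

#' Cluster samples into copy-number genotype groups
#'
#' Fits Gaussian mixture models with the spherical, equal-volume covariance
#' constraint (mclust model "EII"; shared `sigma^2 I` across components) to
#' the rows of the CNVR-restricted segmentation-value matrix, for component
#' counts `G = 1..9` (capped at `M - 1` when fewer than 10 samples). The
#' number of groups is chosen by the mclust BIC, `2 loglik - k log(M)`,
#' maximized; labels are the maximum-a-posteriori assignments. For a
#' single-column matrix the one-dimensional equal-variance model "E" (the
#' 1-D analogue of EII) is used.
#'
#' @param x Numeric matrix, samples x sub-regions (a `seg_matrix` restricted
#'   to one CNVR), or a `seg_matrix` object.
#' @param g_max Largest candidate component count (default 9).
#' @return An object of class `group_assignment`: list with `labels`
#'   (per-sample group index in `1..G`), `G`, `bic_trace` (BIC per candidate
#'   `G`; `NA` where the fit did not converge) and `means` (G x N matrix of
#'   component means).
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_samples <- function(x, g_max = 9) {
  if (inherits(x, "seg_matrix")) x <- x$values
  x <- as.matrix(x)
  m <- nrow(x)
  if (m < 2) {
    warning("fewer than 2 samples; assigning a single group")
    return(structure(list(labels = rep(1L, m), G = 1L,
                          bic_trace = stats::setNames(NA_real_, "1"),
                          means = matrix(colMeans(x), 1)),
                     class = "group_assignment"))
  }
  if (all(abs(sweep(x, 2, x[1, ])) < 1e-12)) {
    # identical rows: one degenerate component
    return(structure(list(labels = rep(1L, m), G = 1L,
                          bic_trace = stats::setNames(NA_real_, "1"),
                          means = matrix(x[1, ], 1)),
                     class = "group_assignment"))
  }
  g_range <- 1:min(g_max, max(1L, m - 1L))
  model <- if (ncol(x) == 1L) "E" else "EII"
  dat <- if (ncol(x) == 1L) x[, 1] else x
  fit <- tryCatch(
    suppressWarnings(
      mclust::Mclust(dat, G = g_range, modelNames = model,
                     verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixture model failed to converge for all G; single group used")
    return(structure(list(labels = rep(1L, m), G = 1L,
                          bic_trace = stats::setNames(
                            rep(NA_real_, length(g_range)), g_range),
                          means = matrix(colMeans(x), 1)),
                     class = "group_assignment"))
  }
  bic <- stats::setNames(as.numeric(fit$BIC[, model][as.character(g_range)]),
                         g_range)
  mu <- fit$parameters$mean
  means <- if (is.null(dim(mu))) matrix(mu, ncol = 1) else t(mu)
  structure(list(labels = as.integer(fit$classification), G = fit$G,
                 bic_trace = bic, means = means),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> G = %d; group sizes: %s\n", x$G,
              paste(tabulate(x$labels, x$G), collapse = ", ")))
  invisible(x)
}
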