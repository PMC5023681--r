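## Scoring of calls against simulation truth: TPR / FDR / CR under the
## +/-10 bp matching radius, and the sample-size resampling experiment.

#' Evaluate breakpoint calls against truth
#'
#' A predicted breakpoint is true if it lies within `radius` of the same
#' sample's truth breakpoint of the same side (left/right) and
#' copy-number state; matching is one-to-one greedy by distance so a single
#' truth breakpoint cannot credit several predictions. A sample is a "true
#' predicted sample" if it is normal and predicted normal, or a carrier
#' predicted with the correct state and both breakpoints true. When a
#' `focus` interval is given, truth events and predicted breakpoints
#' outside it are ignored.
#'
#' * TPR = true predicted breakpoints / all truth breakpoints
#' * FDR = falsely predicted breakpoints / all predicted breakpoints
#' * CR  = called SVs (both breakpoints true) / true SVs
#'
#' @param calls A [call_cohort()] / [kernbreak()] result, or a data frame
#'   with columns `sample`, `state`, `left`, `right` (carriers only).
#' @param truth Data frame `sample`, `type`, `left`, `right` (carrier
#'   events only; samples absent from it are normals).
#' @param radius Matching radius in bp (default 10).
#' @param focus Optional `c(lo, hi)` evaluation interval.
#' @param samples All sample ids in the analysis (needed to score normal
#'   samples; inferred from a results object).
#' @return An object of class `eval_report`: list with `tpr`, `fdr`, `cr`,
#'   counts, a per-breakpoint `distances` table and per-sample `verdicts`.
#' @export
evaluate_calls <- function(calls, truth, radius = 10, focus = NULL,
                           samples = NULL) {
  if (inherits(calls, "kernbreak_result")) calls <- calls$calls
  if (inherits(calls, "kernbreak_calls")) {
    if (is.null(samples)) samples <- calls$sample_ids
    calls <- calls$calls
  }
  if (is.null(samples))
    samples <- unique(c(calls$sample, truth$sample))
  if (nrow(truth) == 0) stop("empty truth set")
  truth <- truth[order(truth$sample), , drop = FALSE]
  if (!is.null(focus)) {
    truth <- truth[truth$left >= focus[1] & truth$right <= focus[2], ,
                   drop = FALSE]
  }
  calls <- calls[calls$state != "NORMAL", , drop = FALSE]
  dist_rows <- list(); verdicts <- logical(length(samples))
  n_true <- n_pred <- n_match <- n_sv_called <- 0L
  for (si in seq_along(samples)) {
    s <- samples[si]
    tr <- truth[truth$sample == s, , drop = FALSE]
    cl <- calls[calls$sample == s, , drop = FALSE]
    sample_ok <- TRUE
    for (side in c("left", "right")) {
      tpos <- tr[[side]]; tstate <- tr$type
      cpos <- cl[[side]]; cstate <- cl$state
      in_focus <- if (is.null(focus)) rep(TRUE, length(cpos))
                  else cpos >= focus[1] & cpos <= focus[2]
      cpos <- cpos[in_focus]; cstate <- cstate[in_focus]
      n_true <- n_true + length(tpos)
      n_pred <- n_pred + length(cpos)
      matched_t <- logical(length(tpos))
      matched_c <- logical(length(cpos))
      if (length(tpos) && length(cpos)) {
        cand <- expand.grid(ti = seq_along(tpos), ci = seq_along(cpos))
        cand$d <- abs(tpos[cand$ti] - cpos[cand$ci])
        cand <- cand[cand$d <= radius &
                     tstate[cand$ti] == cstate[cand$ci], , drop = FALSE]
        for (r in order(cand$d)) {
          ti <- cand$ti[r]; ci <- cand$ci[r]
          if (!matched_t[ti] && !matched_c[ci]) {
            matched_t[ti] <- matched_c[ci] <- TRUE
            n_match <- n_match + 1L
            dist_rows[[length(dist_rows) + 1L]] <- data.frame(
              sample = s, side = side, predicted = cpos[ci],
              truth = tpos[ti], dist = cand$d[r],
              stringsAsFactors = FALSE)
          }
        }
      }
      if (side == "left") ml <- matched_t else mr <- matched_t
      if (any(!matched_c) || any(!matched_t)) sample_ok <- FALSE
    }
    # SVs with both breakpoints true (paired by row order: one event per
    # truth row)
    if (nrow(tr)) n_sv_called <- n_sv_called + sum(ml & mr)
    verdicts[si] <- if (nrow(tr) == 0) nrow(cl) == 0 else sample_ok
  }
  distances <- if (length(dist_rows)) do.call(rbind, dist_rows) else
    data.frame(sample = character(), side = character(),
               predicted = numeric(), truth = numeric(), dist = numeric(),
               stringsAsFactors = FALSE)
  structure(list(
    tpr = if (n_true) n_match / n_true else NA_real_,
    fdr = if (n_pred) (n_pred - n_match) / n_pred else 0,
    cr = if (nrow(truth)) n_sv_called / nrow(truth) else NA_real_,
    n_true_bp = n_true, n_pred_bp = n_pred, n_matched = n_match,
    distances = distances,
    verdicts = data.frame(sample = samples, true_predicted = verdicts,
                          stringsAsFactors = FALSE)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> TPR = %.3f  FDR = %.3f  CR = %.3f\n",
              x$tpr, x$fdr, x$cr))
  cat(sprintf("  %d/%d true breakpoints matched; %d predicted\n",
              x$n_matched, x$n_true_bp, x$n_pred_bp))
  invisible(x)
}

#' Sample-size resampling experiment
#'
#' Draws sub-cohorts of each requested size without replacement, re-runs
#' the cohort-level pipeline stages on each draw (per-sample profiles are
#' reused; they do not depend on cohort composition), and reports the
#' 25/50/75 percent quantiles of TPR and FDR per size.
#'
#' @param profiles A [profile_cohort()] result for the full cohort.
#' @param truth Truth table as in [evaluate_calls()].
#' @param sizes Sub-cohort sizes (default `c(100, 50, 25, 10, 5)`).
#' @param n_rep Draws per size (default 250).
#' @param config A [kb_config()] used for each re-run; its `seed` is
#'   ignored here so replicates differ.
#' @param radius,focus Passed to [evaluate_calls()].
#' @param seed Seed for the draws (and downstream bootstraps).
#' @return An object of class `resample_table`: data frame with one row
#'   per size and quantile columns for TPR and FDR; raw per-replicate
#'   values in `attr(, "replicates")`.
#' @export
resample_experiment <- function(profiles, truth,
                                sizes = c(100, 50, 25, 10, 5),
                                n_rep = 250, config = profiles$config,
                                radius = 10, focus = NULL, seed = NULL) {
  m <- length(profiles$sample_ids)
  if (any(sizes > m))
    stop("requested size exceeds cohort size (", m, ")")
  if (!is.null(seed)) set.seed(seed)
  config$seed <- NULL
  reps <- list()
  for (size in sizes) {
    for (r in seq_len(n_rep)) {
      idx <- sample.int(m, size)
      sub <- subset_profiles(profiles, idx)
      res <- call_cohort(sub, config)
      ev <- evaluate_calls(res, truth, radius = radius, focus = focus,
                           samples = sub$sample_ids)
      reps[[length(reps) + 1L]] <- data.frame(
        size = size, rep = r, tpr = ev$tpr, fdr = ev$fdr)
    }
  }
  reps <- do.call(rbind, reps)
  q <- function(v) stats::quantile(v, c(.25, .5, .75), na.rm = TRUE)
  tab <- do.call(rbind, lapply(sizes, function(sz) {
    sel <- reps[reps$size == sz, ]
    data.frame(size = sz, tpr_q25 = q(sel$tpr)[1], tpr_q50 = q(sel$tpr)[2],
               tpr_q75 = q(sel$tpr)[3], fdr_q25 = q(sel$fdr)[1],
               fdr_q50 = q(sel$fdr)[2], fdr_q75 = q(sel$fdr)[3])
  }))
  rownames(tab) <- NULL
  structure(tab, class = c("resample_table", "data.frame"),
            replicates = reps)
}
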