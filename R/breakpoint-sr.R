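## Split-read stage: soft-clip kernel score and base-resolution refinement.

#' Soft-clip kernel score for candidate positions
#'
#' `score(P_j) = sum_k support_k * dnorm(x_k, mu_j, sigma)` over the pooled
#' clip positions `x_k`; positions where many reads are clipped, or whose
#' immediate neighbours are, score highest. With the default
#' `sigma = 0.5` bp the kernel is nearly a delta function, so only clips
#' within a base or two of the candidate contribute.
#'
#' @param pos Clip junction coordinates (bp).
#' @param support Number of reads clipped at each position.
#' @param candidates Positions at which to evaluate the score.
#' @param sigma Kernel standard deviation in bp (default 0.5).
#' @return Numeric vector of scores, one per candidate.
#' @export
sr_scores <- function(pos, support, candidates, sigma = 0.5) {
  stopifnot(sigma > 0, length(pos) == length(support))
  if (length(pos) == 0) return(rep(0, length(candidates)))
  k <- stats::dnorm(outer(pos, candidates, "-"), sd = sigma)
  as.vector(crossprod(k, support))
}

# Pick the top-scoring clip position for one breakpoint side, or NA when
# no qualifying clip lies in the search window.
pick_sr_position <- function(pool, side, center, epsilon, sigma,
                             min_support) {
  cand <- pool[pool$side == side & pool$support >= min_support &
               abs(pool$pos - center) <= epsilon, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_real_)
  sc <- sr_scores(cand$pos, cand$support, cand$pos, sigma)
  # ties: closest to the read-depth coordinate, then smallest coordinate
  ord <- order(-sc, abs(cand$pos - center), cand$pos)
  cand$pos[ord[1]]
}

#' Refine read-depth breakpoints with split-read evidence
#'
#' Pools soft-clip records from all samples of a group and searches
#' `MedLeft +/- epsilon_open` and `MedRight +/- epsilon_open` (closed
#' windows) for the top-scoring clip position of the junction-consistent
#' side. At a deletion's left breakpoint reads run off the junction
#' rightwards, so only `RIGHT_CLIP` records qualify, and only `LEFT_CLIP`
#' records at its right breakpoint; at a tandem-duplication junction the
#' clip orientations are mirrored (`LEFT_CLIP` left, `RIGHT_CLIP` right).
#' A side with no qualifying clip keeps its read-depth coordinate
#' (source `"RD"`).
#'
#' Reported breakpoints follow the convention left = first affected base,
#' right = last affected base; junction coordinates on the right side
#' (first base after the event) are therefore shifted down by one.
#'
#' @param rd An [bootstrap_breakpoints()] estimate.
#' @param tables A `splitread_table`, or list of them (one per group
#'   sample); pooled by summing support at identical (position, side).
#' @param state `"DEL"` or `"DUP"` (the group's copy-number state).
#' @param epsilon_open Search half-width in bp (default: window size at the
#'   usual operating point).
#' @param sigma Split-read kernel standard deviation (default 0.5 bp).
#' @param min_support Minimum clip support per position (default 1).
#' @return An object of class `breakpoint_call`: list with `state`,
#'   `left_bp`, `right_bp`, `left_source`/`right_source` (`"SR"` or
#'   `"RD"`), and `support` (clip reads at the chosen positions).
#' @export
refine_breakpoints <- function(rd, tables, state = c("DEL", "DUP"),
                               epsilon_open = 500, sigma = 0.5,
                               min_support = 1) {
  state <- match.arg(state)
  if (rd$med_left >= rd$med_right)
    stop("read-depth estimate has med_left >= med_right")
  pool <- pool_splitreads(tables)
  left_side <- if (state == "DEL") "RIGHT_CLIP" else "LEFT_CLIP"
  right_side <- if (state == "DEL") "LEFT_CLIP" else "RIGHT_CLIP"
  lp <- pick_sr_position(pool, left_side, rd$med_left, epsilon_open,
                         sigma, min_support)
  rp <- pick_sr_position(pool, right_side, rd$med_right, epsilon_open,
                         sigma, min_support)
  sup <- 0L
  if (!is.na(lp))
    sup <- sup + sum(pool$support[pool$side == left_side & pool$pos == lp])
  if (!is.na(rp))
    sup <- sup + sum(pool$support[pool$side == right_side & pool$pos == rp])
  structure(list(
    state = state,
    left_bp = if (is.na(lp)) rd$med_left else lp,
    right_bp = (if (is.na(rp)) rd$med_right else rp) - 1,
    left_source = if (is.na(lp)) "RD" else "SR",
    right_source = if (is.na(rp)) "RD" else "SR",
    support = sup),
    class = "breakpoint_call")
}

#' Pool split-read tables over samples
#'
#' @param tables A `splitread_table` or a list of them.
#' @return A data frame `pos`, `side`, `support` with support summed at
#'   identical (position, side) pairs.
#' @export
pool_splitreads <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  all <- do.call(rbind, lapply(tables, function(t)
    as.data.frame(t)[c("pos", "side", "support")]))
  if (is.null(all) || nrow(all) == 0)
    return(data.frame(pos = numeric(), side = character(),
                      support = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(support ~ pos + side, all, sum)
  agg[order(agg$pos, agg$side), c("pos", "side", "support")]
}

#' @export
print.breakpoint_call <- function(x, ...) {
  cat(sprintf("<breakpoint_call> %s %s-%s (%s/%s, support %d)\n", x$state,
              format(x$left_bp), format(x$right_bp), x$left_source,
              x$right_source, x$support))
  invisible(x)
}
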