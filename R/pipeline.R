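## End-to-end orchestration: per-sample profiling (stage A), cohort-level
## calling (stage B), and the top-level entry point.

#' Pipeline configuration
#'
#' Defaults mirror the method's standard operating point: 500 bp windows,
#' CNVR thresholds +/-0.25 on the standardized scale, a read-depth kernel
#' standard deviation of one third of the window size, a split-read kernel
#' standard deviation of 0.5 bp, and a split-read search half-width of one
#' window.
#'
#' @param window_size Window width in bp (default 500).
#' @param dup_threshold,del_threshold CNVR call thresholds (default
#'   +0.25 / -0.25).
#' @param sigma_rd Read-depth kernel sd in bp (default `window_size / 3`).
#' @param sigma_sr Split-read kernel sd in bp (default 0.5).
#' @param epsilon_open Split-read search half-width in bp (default
#'   `window_size`).
#' @param n_resample Bootstrap replicates for the read-depth stage
#'   (default 100).
#' @param count_threshold Minimum CNVR carrier count (default 1; around
#'   10 percent of the sample size is recommended for population cohorts).
#' @param min_mapq Minimum mapping quality (default 0).
#' @param min_clip_len Minimum soft-clip length (default 10).
#' @param min_support Minimum clip support per split-read position
#'   (default 1).
#' @param drop_duplicates Honor the SAM duplicate flag (default `TRUE`).
#' @param standardize_method `"median_window"` (default) or `"cnvrd2"`,
#'   see [standardize()].
#' @param seed Optional seed applied at the start of cohort-level calling
#'   for reproducible bootstraps.
#' @return A list of class `kb_config`.
#' @export
kb_config <- function(window_size = 500, dup_threshold = 0.25,
                      del_threshold = -0.25, sigma_rd = window_size / 3,
                      sigma_sr = 0.5, epsilon_open = window_size,
                      n_resample = 100, count_threshold = 1, min_mapq = 0,
                      min_clip_len = 10, min_support = 1,
                      drop_duplicates = TRUE,
                      standardize_method = "median_window", seed = NULL) {
  stopifnot(sigma_rd > 0, sigma_sr > 0, epsilon_open >= sigma_sr,
            n_resample >= 1, del_threshold < 0, dup_threshold > 0)
  structure(as.list(environment()), class = "kb_config")
}

#' Per-sample profiling of an alignment cohort (stage A)
#'
#' Extracts window counts and split-read tables for each sample, applies
#' GC (and mappability) correction when the tracks are supplied,
#' standardizes, and segments each sample. The result is independent of
#' cohort composition, so subsets of it can be re-analysed with
#' [call_cohort()] without touching the alignments again.
#'
#' @param files Paths to coordinate-sorted, indexed BAM (or SAM) files,
#'   one per sample.
#' @param grid A [window_grid()].
#' @param config A [kb_config()].
#' @param gc Per-window GC fractions, a reference (FASTA path or
#'   `DNAStringSet`) from which to compute them, or `NULL` to skip GC
#'   correction.
#' @param mappability Per-window mappability values, or `NULL`.
#' @param sample_ids Sample labels (default: file base names without
#'   extension).
#' @return An object of class `cohort_profiles`: list with `grid`, `std`
#'   (samples x windows standardized matrix), `segs`, `splits`,
#'   `sample_ids` and `config`.
#' @export
profile_cohort <- function(files, grid, config = kb_config(), gc = NULL,
                           mappability = NULL,
                           sample_ids = sub("\\.(bam|sam)$", "",
                                            basename(files),
                                            ignore.case = TRUE)) {
  stopifnot(length(files) >= 1, length(sample_ids) == length(files))
  if (length(files) < 5)
    warning("fewer than 5 samples; group-based breakpoint imputation ",
            "works best with at least 5")
  if (!is.null(gc) && !is.numeric(gc)) gc <- compute_gc_track(gc, grid)
  counts <- matrix(0, length(files), grid$n,
                   dimnames = list(sample_ids, window_labels(grid)))
  splits <- vector("list", length(files))
  for (i in seq_along(files)) {
    sp <- scan_profile(files[i], grid, min_mapq = config$min_mapq,
                       drop_duplicates = config$drop_duplicates,
                       min_clip_len = config$min_clip_len,
                       sample_id = sample_ids[i])
    rc <- sp$counts
    if (!is.null(gc)) {
      rc$gc_fraction <- gc
      rc$mappability <- mappability
      rc <- bias_correct(rc, mode = if (is.null(mappability)) "gc"
                                    else "gc+mappability")
    }
    counts[i, ] <- rc$counts
    splits[[i]] <- sp$splits
  }
  std <- standardize(counts, method = config$standardize_method)
  segs <- lapply(seq_len(nrow(std)), function(i) segment_sample(std[i, ]))
  names(segs) <- names(splits) <- sample_ids
  structure(list(grid = grid, std = std, segs = segs, splits = splits,
                 sample_ids = sample_ids, config = config),
            class = "cohort_profiles")
}

#' Restrict cohort profiles to a sample subset
#'
#' @param profiles A [profile_cohort()] result.
#' @param idx Sample indices or names.
#' @return A `cohort_profiles` object over the subset.
#' @export
subset_profiles <- function(profiles, idx) {
  if (is.character(idx)) idx <- match(idx, profiles$sample_ids)
  structure(list(grid = profiles$grid,
                 std = profiles$std[idx, , drop = FALSE],
                 segs = profiles$segs[idx], splits = profiles$splits[idx],
                 sample_ids = profiles$sample_ids[idx],
                 config = profiles$config),
            class = "cohort_profiles")
}

#' @export
print.cohort_profiles <- function(x, ...) {
  cat(sprintf("<cohort_profiles> %d samples x %d windows (%s:%d-%d)\n",
              length(x$sample_ids), x$grid$n, x$grid$chrom,
              x$grid$region_start, x$grid$region_end))
  invisible(x)
}

#' Cohort-level CNVR calling and breakpoint estimation (stage B)
#'
#' Builds the shared sub-region partition from all samples' change-points,
#' calls CNVRs by thresholds, clusters the samples of each CNVR into
#' copy-number genotype groups, estimates each non-normal group's
#' breakpoints from the read-depth kernel score with bootstrap resampling,
#' and refines them to base resolution from the group's pooled soft-clip
#' records. Samples inherit their group's breakpoints (the imputation
#' step that rescues low-coverage samples) after a per-sample check that
#' the sample's own mean segmentation value between those breakpoints
#' crosses the calling threshold: group evidence localizes the event,
#' while each sample's copy-number status remains its own.
#'
#' @param profiles A [profile_cohort()] result (or subset).
#' @param config A [kb_config()]; defaults to the one stored in
#'   `profiles`.
#' @return An object of class `kernbreak_calls`: list with `calls` (data
#'   frame, one row per carrier sample per CNVR: `sample`, `cnvr_id`,
#'   `group`, `state`, `left`, `right`, `left_source`, `right_source`,
#'   `support`), `cnvrs`, `groups` (per-CNVR clustering and per-group
#'   read-depth estimates), `partition`, `sample_ids` and `config`.
#' @export
call_cohort <- function(profiles, config = profiles$config) {
  stopifnot(inherits(profiles, "cohort_profiles"))
  if (!is.null(config$seed)) set.seed(config$seed)
  grid <- profiles$grid
  partition <- build_partition(profiles$segs, grid)
  sm <- seg_matrix(profiles$segs, partition, grid, profiles$sample_ids)
  cn <- call_cnvrs(sm, dup_threshold = config$dup_threshold,
                   del_threshold = config$del_threshold,
                   count_threshold = config$count_threshold)
  calls <- list(); groups <- list()
  for (ci in seq_len(nrow(cn$cnvrs))) {
    sub <- cn$cnvrs$first_sub[ci]:cn$cnvrs$last_sub[ci]
    v <- sm$values[, sub, drop = FALSE]
    bounds <- partition$boundaries[c(sub, sub[length(sub)] + 1L)]
    ga <- cluster_samples(v)
    ginfo <- list(assignment = ga, rd = vector("list", ga$G),
                  state = character(ga$G))
    for (g in seq_len(ga$G)) {
      rows <- which(ga$labels == g)
      if (length(rows) == 0) { ginfo$state[g] <- "NORMAL"; next }
      padded <- pad_group_matrix(v[rows, , drop = FALSE], bounds)
      rd <- tryCatch(
        bootstrap_breakpoints(padded, sigma = config$sigma_rd,
                              n_resample = config$n_resample),
        error = function(e) NULL)
      if (is.null(rd)) { ginfo$state[g] <- "NORMAL"; next }
      state <- group_state(v[rows, , drop = FALSE], bounds, rd, config)
      ginfo$rd[[g]] <- rd
      ginfo$state[g] <- state
      if (state == "NORMAL") next
      bp <- refine_breakpoints(rd, profiles$splits[rows], state,
                               epsilon_open = config$epsilon_open,
                               sigma = config$sigma_sr,
                               min_support = config$min_support)
      # group evidence localizes the breakpoints, but each member's CN
      # status is its own: a sample only inherits the call if its own
      # mean segmentation value between the group's breakpoints crosses
      # the calling threshold (guards against mixed groups when the
      # component cap binds)
      own <- sample_means(v[rows, , drop = FALSE], bounds, rd)
      keep <- if (state == "DUP") own > config$dup_threshold
              else own < config$del_threshold
      rows <- rows[keep]
      if (length(rows) == 0) next
      calls[[length(calls) + 1L]] <- data.frame(
        sample = profiles$sample_ids[rows], cnvr_id = cn$cnvrs$cnvr_id[ci],
        group = g, state = state, left = bp$left_bp, right = bp$right_bp,
        left_source = bp$left_source, right_source = bp$right_source,
        support = bp$support, stringsAsFactors = FALSE)
    }
    groups[[ci]] <- ginfo
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample = character(), cnvr_id = integer(),
               group = integer(), state = character(), left = numeric(),
               right = numeric(), left_source = character(),
               right_source = character(), support = integer(),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(calls = calls, cnvrs = cn$cnvrs, groups = groups,
                 partition = partition, states = cn$states,
                 sample_ids = profiles$sample_ids, config = config),
            class = "kernbreak_calls")
}

# Width-weighted mean of each row's segmentation values between the
# read-depth breakpoint pair.
sample_means <- function(v, bounds, rd) {
  s <- bounds[-length(bounds)]; e <- bounds[-1] - 1
  w <- e - s + 1
  inside <- s >= rd$med_left & e < rd$med_right
  if (!any(inside)) inside <- rep(TRUE, length(w))
  as.vector(v[, inside, drop = FALSE] %*% w[inside]) / sum(w[inside])
}

# The group's state: its mean profile between the breakpoints,
# thresholded.
group_state <- function(v, bounds, rd, config) {
  m <- mean(sample_means(v, bounds, rd))
  if (m > config$dup_threshold) "DUP"
  else if (m < config$del_threshold) "DEL"
  else "NORMAL"
}

#' Run the full breakpoint-detection pipeline
#'
#' Convenience wrapper: [profile_cohort()] followed by [call_cohort()].
#'
#' @inheritParams profile_cohort
#' @return An object of class `kernbreak_result`: list with `calls` (the
#'   [call_cohort()] result) and `profiles`.
#' @examples
#' \dontrun{
#' grid <- window_grid("sim1", 1, 1e6, 500)
#' res <- kernbreak(bam_files, grid, kb_config(seed = 1))
#' summary(res)
#' }
#' @export
kernbreak <- function(files, grid, config = kb_config(), gc = NULL,
                      mappability = NULL,
                      sample_ids = sub("\\.(bam|sam)$", "",
                                       basename(files),
                                       ignore.case = TRUE)) {
  profiles <- profile_cohort(files, grid, config, gc = gc,
                             mappability = mappability,
                             sample_ids = sample_ids)
  calls <- call_cohort(profiles, config)
  structure(list(calls = calls, profiles = profiles),
            class = "kernbreak_result")
}

#' @export
print.kernbreak_calls <- function(x, ...) {
  cat(sprintf("<kernbreak_calls> %d CNVR(s), %d carrier call(s), %d samples\n",
              nrow(x$cnvrs), nrow(x$calls), length(x$sample_ids)))
  invisible(x)
}

#' @export
print.kernbreak_result <- function(x, ...) {
  print(x$calls)
  invisible(x)
}

#' @export
summary.kernbreak_result <- function(object, ...) {
  calls <- object$calls$calls
  cat(sprintf("Samples: %d   Windows: %d x %d bp\n",
              length(object$calls$sample_ids), object$profiles$grid$n,
              object$profiles$grid$window_size))
  cat(sprintf("CNVRs: %d\n", nrow(object$calls$cnvrs)))
  if (nrow(calls)) {
    per_group <- unique(calls[c("cnvr_id", "group", "state", "left",
                                "right", "left_source", "right_source",
                                "support")])
    per_group$n_samples <- as.integer(table(
      paste(calls$cnvr_id, calls$group))[
        paste(per_group$cnvr_id, per_group$group)])
    cat("Per-group breakpoints:\n")
    print(per_group, row.names = FALSE)
  } else cat("No carrier groups called.\n")
  invisible(object)
}
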