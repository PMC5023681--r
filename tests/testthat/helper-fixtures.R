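# Shared fixtures: hand-built SAM files and an independent full-scan tally
# used as the oracle for the alignment readers.

# Write a SAM file from a record table (qname, flag, pos, mapq, cigar).
write_test_sam <- function(records, path, chrom = "chrT", len = 100000L) {
  records <- records[order(records$pos), , drop = FALSE]
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, len),
             paste(records$qname, records$flag, chrom, records$pos,
                   records$mapq, records$cigar, "*", 0L, 0L, "*", "*",
                   sep = "\t"))
  writeLines(lines, path)
  path
}

sam_record <- function(qname, pos, cigar, flag = 0L, mapq = 60L) {
  data.frame(qname = qname, flag = flag, pos = pos, mapq = mapq,
             cigar = cigar, stringsAsFactors = FALSE)
}

# Naive window tally straight from the SAM text; deliberately independent
# of the package's readers.
naive_window_tally <- function(sam_path, grid, min_mapq = 0,
                               drop_duplicates = TRUE) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- integer(grid$n)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2]); pos <- as.integer(f[4])
    mapq <- as.integer(f[5])
    if (bitwAnd(flag, 4L) > 0) next                  # unmapped
    if (bitwAnd(flag, 256L) > 0 || bitwAnd(flag, 2048L) > 0) next
    if (drop_duplicates && bitwAnd(flag, 1024L) > 0) next
    if (mapq < min_mapq) next
    if (f[3] != grid$chrom) next
    if (pos < grid$region_start || pos > grid$region_end) next
    w <- (pos - grid$region_start) %/% grid$window_size + 1
    counts[w] <- counts[w] + 1L
  }
  counts
}

# Naive clip-record scan from SAM text (terminal S operations only).
naive_clip_scan <- function(sam_path, grid, min_clip_len = 10) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2]); pos <- as.integer(f[4]); cg <- f[6]
    if (bitwAnd(flag, 4L) > 0 || bitwAnd(flag, 256L) > 0 ||
        bitwAnd(flag, 2048L) > 0 || bitwAnd(flag, 1024L) > 0) next
    toks <- regmatches(cg, gregexpr("[0-9]+[A-Z=]", cg))[[1]]
    len <- as.integer(sub(".$", "", toks))
    op <- substring(toks, nchar(toks))
    refw <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    if (op[1] == "S" && len[1] >= min_clip_len)
      out[[length(out) + 1L]] <- c(pos, 1L)
    if (op[length(op)] == "S" && len[length(op)] >= min_clip_len)
      out[[length(out) + 1L]] <- c(pos + refw, 2L)
  }
  if (!length(out))
    return(data.frame(pos = integer(), side = character(),
                      support = integer()))
  m <- do.call(rbind, out)
  d <- data.frame(pos = m[, 1],
                  side = c("LEFT_CLIP", "RIGHT_CLIP")[m[, 2]])
  d <- d[d$pos >= grid$region_start & d$pos <= grid$region_end, ,
         drop = FALSE]
  agg <- aggregate(list(support = rep(1L, nrow(d))), d[c("pos", "side")],
                   sum)
  agg[order(agg$pos, agg$side), ]
}

# Brute-force kernel score oracles (double loops, no vectorization).
brute_rd_scores <- function(values, positions, sigma,
                            candidates = positions) {
  w <- matrix(0, nrow(values), length(positions))
  for (i in seq_len(nrow(values)))
    for (k in seq_along(positions))
      w[i, k] <- abs(values[i, k + 1] - values[i, k])
  out <- numeric(length(candidates))
  for (j in seq_along(candidates))
    for (i in seq_len(nrow(values)))
      for (k in seq_along(positions))
        out[j] <- out[j] + w[i, k] *
          dnorm(positions[k], candidates[j], sigma)
  out
}

brute_sr_scores <- function(pos, support, candidates, sigma) {
  out <- numeric(length(candidates))
  for (j in seq_along(candidates))
    for (k in seq_along(pos))
      out[j] <- out[j] + support[k] * dnorm(pos[k], candidates[j], sigma)
  out
}

# Adjusted Rand index between two labelings (direct from the pair-count
# definition).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_ij <- si * sj / n2
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}
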