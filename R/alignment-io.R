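## Extraction of windowed read counts and soft-clip evidence from SAM/BAM.
## External coordinates are 1-based inclusive throughout (SAM convention).

#' Resolve an alignment file to an indexed BAM
#'
#' BAM files are used as-is (an index `.bai` must exist alongside). SAM text
#' files (extension `.sam`) are converted, sorted and indexed into the
#' session temporary directory; conversions are cached per input path.
#'
#' @param file Path to a `.bam` (indexed) or `.sam` file.
#' @return Path to an indexed BAM file.
#' @keywords internal
ensure_bam <- function(file) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    key <- paste0("kb_", substr(tools::md5sum(file), 1, 12), "_",
                  sub("\\.sam$", "", basename(file), ignore.case = TRUE))
    dest <- file.path(tempdir(), key)
    bam <- paste0(dest, ".bam")
    if (!file.exists(bam) || !file.exists(paste0(bam, ".bai")))
      bam <- Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                              indexDestination = TRUE)
    return(bam)
  }
  idx <- paste0(file, ".bai")
  idx2 <- sub("\\.bam$", ".bai", file, ignore.case = TRUE)
  if (!file.exists(idx) && !file.exists(idx2))
    stop("BAM index (.bai) not found for: ", file,
         " (index the file, e.g. with Rsamtools::indexBam)")
  file
}

check_chrom <- function(bam, chrom) {
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!chrom %in% names(targets))
    stop("chromosome '", chrom, "' absent from alignment header of ",
         basename(bam))
  invisible(targets[[chrom]])
}

scan_region <- function(bam, grid, what, min_mapq, drop_duplicates) {
  which <- IRanges::IRangesList(
    IRanges::IRanges(grid$region_start, grid$region_end))
  names(which) <- grid$chrom
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (drop_duplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = what, which = which,
    mapqFilter = if (min_mapq > 0) min_mapq else NA_integer_)
  Rsamtools::scanBam(bam, param = param)[[1]]
}

#' Count reads per window
#'
#' Each retained alignment (primary, mapped, optionally non-duplicate,
#' mapping quality at least `min_mapq`) is assigned to exactly one window by
#' its leftmost aligned base.
#'
#' @param file Indexed BAM (or SAM) file, coordinate-sorted.
#' @param grid A [window_grid()].
#' @param min_mapq Minimum mapping quality (default 0, keep all).
#' @param drop_duplicates Exclude reads carrying the SAM duplicate flag
#'   (default `TRUE`).
#' @param sample_id Label stored with the counts (default: file name).
#' @return An object of class `raw_counts`: list with `sample_id`, integer
#'   `counts` (one per window), and `NULL` placeholders for `gc_fraction`
#'   and `mappability` annotation (see [compute_gc_track()]).
#' @export
count_reads <- function(file, grid, min_mapq = 0, drop_duplicates = TRUE,
                        sample_id = basename(file)) {
  bam <- ensure_bam(file)
  check_chrom(bam, grid$chrom)
  res <- scan_region(bam, grid, what = "pos", min_mapq, drop_duplicates)
  idx <- window_index(grid, res$pos)
  idx <- idx[!is.na(idx)]
  structure(
    list(sample_id = sample_id, counts = tabulate(idx, nbins = grid$n),
         gc_fraction = NULL, mappability = NULL),
    class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  cat(sprintf("<raw_counts> sample %s: %d windows, %d reads\n",
              x$sample_id, length(x$counts), sum(x$counts)))
  invisible(x)
}

## --- CIGAR arithmetic -----------------------------------------------------
## Vectorized over the (few) unique CIGAR strings seen in a file.

cigar_valid <- function(cigar) {
  grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
}

parse_one_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = substring(toks, nchar(toks)))
}

# Per-CIGAR: reference span, leading soft-clip length, trailing soft-clip
# length. Returns a 3-column matrix aligned with `cigar`.
cigar_features <- function(cigar) {
  uc <- unique(cigar)
  feat <- vapply(uc, function(cg) {
    p <- parse_one_cigar(cg)
    ref <- sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
    op <- p$op[p$op != "H"]  # hard clips are transparent to soft-clip sides
    len <- p$len[p$op != "H"]
    lead <- if (length(op) && op[1] == "S") len[1] else 0L
    trail <- if (length(op) && op[length(op)] == "S") len[length(op)] else 0L
    c(ref, lead, trail)
  }, numeric(3))
  t(feat)[match(cigar, uc), , drop = FALSE]
}

#' Extract soft-clip (split-read) evidence
#'
#' Scans CIGAR strings for terminal soft-clip (`S`) operations of at least
#' `min_clip_len` bases. A trailing clip yields a `RIGHT_CLIP` record at the
#' reference coordinate one past the last aligned base (the junction); a
#' leading clip yields a `LEFT_CLIP` record at the first aligned base.
#' Records at the same (position, side) are aggregated into a support count.
#'
#' @inheritParams count_reads
#' @param min_clip_len Minimum soft-clip length in bases (default 10);
#'   shorter clips, typically base-error noise, are ignored.
#' @return An object of class `splitread_table`: a data frame with columns
#'   `pos`, `side` (`"LEFT_CLIP"`/`"RIGHT_CLIP"`) and `support`, plus a
#'   `sample_id` attribute.
#' @export
extract_splitreads <- function(file, grid, min_clip_len = 10, min_mapq = 0,
                               drop_duplicates = TRUE,
                               sample_id = basename(file)) {
  bam <- ensure_bam(file)
  check_chrom(bam, grid$chrom)
  res <- scan_region(bam, grid, what = c("qname", "pos", "cigar"),
                     min_mapq, drop_duplicates)
  splitreads_from_records(res$pos, res$cigar, res$qname, grid,
                          min_clip_len, sample_id)
}

# One-pass extraction of both window counts and clip records (used by the
# pipeline so each alignment file is scanned once).
scan_profile <- function(file, grid, min_mapq = 0, drop_duplicates = TRUE,
                         min_clip_len = 10, sample_id = basename(file)) {
  bam <- ensure_bam(file)
  check_chrom(bam, grid$chrom)
  res <- scan_region(bam, grid, what = c("qname", "pos", "cigar"),
                     min_mapq, drop_duplicates)
  idx <- window_index(grid, res$pos)
  idx <- idx[!is.na(idx)]
  counts <- structure(
    list(sample_id = sample_id, counts = tabulate(idx, nbins = grid$n),
         gc_fraction = NULL, mappability = NULL),
    class = "raw_counts")
  splits <- splitreads_from_records(res$pos, res$cigar, res$qname, grid,
                                    min_clip_len, sample_id)
  list(counts = counts, splits = splits)
}

splitreads_from_records <- function(pos, cigar, qname, grid, min_clip_len,
                                    sample_id) {
  keep <- !is.na(cigar) & cigar != "*"
  bad <- keep & !cigar_valid(cigar)
  if (any(bad)) {
    warning("skipping ", sum(bad), " read(s) with malformed CIGAR: ",
            paste(utils::head(qname[bad], 5), collapse = ", "))
    keep <- keep & !bad
  }
  pos <- pos[keep]; cigar <- cigar[keep]
  recs <- if (length(pos)) {
    f <- cigar_features(cigar)
    left <- f[, 2] >= min_clip_len
    right <- f[, 3] >= min_clip_len
    data.frame(
      pos = c(pos[left], pos[right] + f[right, 1]),
      side = rep(c("LEFT_CLIP", "RIGHT_CLIP"), c(sum(left), sum(right))),
      stringsAsFactors = FALSE)
  } else {
    data.frame(pos = integer(), side = character(),
               stringsAsFactors = FALSE)
  }
  recs <- recs[recs$pos >= grid$region_start & recs$pos <= grid$region_end, ,
               drop = FALSE]
  agg <- if (nrow(recs)) {
    tab <- stats::aggregate(list(support = rep(1L, nrow(recs))),
                            recs[c("pos", "side")], sum)
    tab[order(tab$pos, tab$side), , drop = FALSE]
  } else {
    data.frame(pos = integer(), side = character(), support = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(agg) <- NULL
  structure(agg, class = c("splitread_table", "data.frame"),
            sample_id = sample_id)
}

#' Per-window GC fraction from a reference FASTA
#'
#' @param reference FASTA path or a [Biostrings::DNAStringSet].
#' @param grid A [window_grid()]; `grid$chrom` must name a FASTA sequence
#'   (the first word of its header line).
#' @return Numeric vector of per-window G+C fractions among non-N bases;
#'   `NA` for all-N windows.
#' @export
compute_gc_track <- function(reference, grid) {
  seqs <- if (inherits(reference, "DNAStringSet")) reference
          else Biostrings::readDNAStringSet(reference)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!grid$chrom %in% names(seqs))
    stop("sequence '", grid$chrom, "' not found in reference")
  s <- seqs[[grid$chrom]]
  if (grid$region_end > length(s))
    stop("grid extends past the end of the reference sequence (",
         length(s), " bp)")
  v <- Biostrings::Views(s, start = grid$starts, end = grid$ends)
  freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "N"))
  denom <- (grid$ends - grid$starts + 1) - freq[, "N"]
  gc <- (freq[, "G"] + freq[, "C"]) / denom
  gc[denom == 0] <- NA_real_
  unname(gc)
}

#' Average a tab-delimited interval track over windows
#'
#' Reads a bedGraph-like file (`chrom start end value`, 0-based half-open
#' starts as in the BED/bedGraph convention) and returns the
#' coverage-weighted mean value per window; windows with no overlapping
#' interval get `NA`.
#'
#' @param path Tab-delimited track file (no header).
#' @param grid A [window_grid()].
#' @return Numeric vector, one value per window.
#' @export
read_track_tsv <- function(path, grid) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("chrom", "start", "end", "value")
  tab <- tab[tab$chrom == grid$chrom, , drop = FALSE]
  num <- den <- numeric(grid$n)
  for (i in seq_len(nrow(tab))) {
    s <- tab$start[i] + 1L  # to 1-based inclusive
    e <- tab$end[i]
    wi <- window_index(grid, max(s, grid$region_start))
    we <- window_index(grid, min(e, grid$region_end))
    if (is.na(wi) || is.na(we)) next
    for (w in wi:we) {
      ov <- min(e, grid$ends[w]) - max(s, grid$starts[w]) + 1
      if (ov > 0) {
        num[w] <- num[w] + ov * tab$value[i]
        den[w] <- den[w] + ov
      }
    }
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
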