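## CNV read simulator: synthetic reference, donor genomes carrying
## deletion / tandem-duplication events, and pre-aligned SAM records whose
## CIGAR strings carry soft-clips at event junctions. Because reads are
## placed back onto the reference analytically, no external aligner is
## needed and the junction evidence is exact.

#' Generate a random reference sequence
#'
#' @param length Sequence length in bp (minimum 10 kb).
#' @param chrom Sequence name (default `"sim1"`).
#' @param gc Baseline GC content (default 0.4, roughly genomic).
#' @param gc_profile Optional data frame `start`, `end`, `gc` overriding
#'   the GC content on given spans, to exercise bias correction.
#' @param seed Optional seed; the sequence is deterministic given it.
#' @param fasta Optional path; when given the sequence is also written as
#'   FASTA.
#' @return A [Biostrings::DNAStringSet] of length 1.
#' @export
sim_reference <- function(length = 1e6, chrom = "sim1", gc = 0.4,
                          gc_profile = NULL, seed = NULL, fasta = NULL) {
  if (length < 1e4) stop("reference length must be at least 10 kb")
  if (!is.null(seed)) set.seed(seed)
  p <- function(g) c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  bases <- sample(names(p(gc)), length, replace = TRUE, prob = p(gc))
  if (!is.null(gc_profile)) {
    for (i in seq_len(nrow(gc_profile))) {
      span <- gc_profile$start[i]:gc_profile$end[i]
      bases[span] <- sample(names(p(gc)), length(span), replace = TRUE,
                            prob = p(gc_profile$gc[i]))
    }
  }
  seqs <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(seqs) <- chrom
  if (!is.null(fasta)) Biostrings::writeXStringSet(seqs, fasta)
  seqs
}

#' Event layout of the benchmark cohort
#'
#' Seven duplication/deletion configurations (nested deletions of 84,780,
#' 20,000, 5,000 and 1,000 bp and tandem duplications of 50,000, 20,000 and
#' 10,000 bp in the middle of a 1 Mb region) plus a normal class, each
#' realized in `n_samples` samples whose coverages sweep 1x..`n_samples`x.
#'
#' @param n_samples Samples per event configuration (default 15, giving a
#'   120-sample cohort).
#' @return Data frame with `label`, `type`, `start`, `end` (1-based
#'   inclusive affected bases; `NA` for the normal class) and `n_samples`.
#' @export
cohort_events <- function(n_samples = 15) {
  data.frame(
    label = c("del1", "del2", "del3", "del4", "dup1", "dup2", "dup3",
              "normal"),
    type = c(rep("DEL", 4), rep("DUP", 3), "NORMAL"),
    start = c(445220, 456000, 460000, 461000, 455000, 456000, 458000, NA),
    end = c(530000, 476000, 465000, 462000, 505000, 476000, 468000, NA),
    n_samples = n_samples, stringsAsFactors = FALSE)
}

#' Evaluation focus interval for an event layout
#'
#' @param layout A [cohort_events()]-style data frame.
#' @param margin Flank added to the union of event spans (default 5000 bp).
#' @return Length-2 numeric `c(lo, hi)`.
#' @export
cohort_focus <- function(layout = cohort_events(), margin = 5000) {
  c(min(layout$start, na.rm = TRUE) - margin,
    max(layout$end, na.rm = TRUE) + margin)
}

# Donor genome block table for a set of non-overlapping events on one
# haplotype-collapsed genome. Columns: ref_start, ref_end, donor_start.
donor_blocks <- function(events, ref_len) {
  segs <- list()
  add <- function(s, e) if (e >= s) segs[[length(segs) + 1L]] <<- c(s, e)
  cur <- 1L
  if (!is.null(events) && nrow(events)) {
    events <- events[order(events$start), , drop = FALSE]
    if (any(events$start >= events$end))
      stop("event start must be less than end")
    if (any(events$start < 1 | events$end > ref_len))
      stop("event outside the reference")
    if (nrow(events) > 1 &&
        any(events$start[-1] <= events$end[-nrow(events)]))
      stop("events must be non-overlapping within one sample")
    for (i in seq_len(nrow(events))) {
      s <- events$start[i]; e <- events$end[i]
      if (events$type[i] == "DEL") {
        add(cur, s - 1L)
        cur <- e + 1L
      } else if (events$type[i] == "DUP") {  # tandem: copy follows original
        add(cur, e)
        add(s, e)
        cur <- e + 1L
      } else stop("unknown event type: ", events$type[i])
    }
  }
  add(cur, ref_len)
  b <- do.call(rbind, segs)
  data.frame(ref_start = b[, 1], ref_end = b[, 2],
             donor_start = cumsum(c(1, (b[, 2] - b[, 1] + 1)))[
               seq_len(nrow(b))])
}

# Map donor-coordinate read starts to reference placements.
# Returns data.frame(pos, cigar, dstart); reads spanning one junction are
# aligned to the block holding the majority of their bases with the
# remainder soft-clipped.
map_donor_reads <- function(d, read_len, blocks) {
  bw <- blocks$ref_end - blocks$ref_start + 1
  dstarts <- blocks$donor_start
  bi <- findInterval(d, dstarts)
  ei <- findInterval(d + read_len - 1, dstarts)
  pos <- blocks$ref_start[bi] + (d - dstarts[bi])
  cigar <- rep(paste0(read_len, "M"), length(d))
  jx <- which(ei != bi)
  for (i in jx) {
    if (ei[i] - bi[i] > 1L) {  # spans >1 junction: clip to the widest block
      ks <- bi[i]:ei[i]
      inb <- pmin(dstarts[ks] + bw[ks] - 1, d[i] + read_len - 1) -
             pmax(dstarts[ks], d[i]) + 1
      k <- ks[which.max(inb)]
      lead <- max(dstarts[k] - d[i], 0)
      aln <- inb[which.max(inb)]
      trail <- read_len - lead - aln
      pos[i] <- blocks$ref_start[k] + max(d[i] - dstarts[k], 0)
      cigar[i] <- paste0(if (lead) paste0(lead, "S"), aln, "M",
                         if (trail) paste0(trail, "S"))
    } else if (blocks$ref_end[bi[i]] + 1 == blocks$ref_start[ei[i]]) {
      # blocks adjacent in reference coordinates (e.g. the downstream edge
      # of a tandem duplication): the read aligns as a full match
      cigar[i] <- paste0(read_len, "M")
    } else {
      b <- dstarts[bi[i]] + bw[bi[i]] - d[i]  # bases in the left block
      r2 <- read_len - b
      if (b >= r2) {
        cigar[i] <- paste0(b, "M", r2, "S")
      } else {
        pos[i] <- blocks$ref_start[ei[i]]
        cigar[i] <- paste0(b, "S", r2, "M")
      }
    }
  }
  data.frame(pos = pos, cigar = cigar, dstart = d)
}

inject_errors <- function(seqs, error_rate) {
  n <- length(seqs); rl <- nchar(seqs[1])
  nerr <- stats::rbinom(1, n * rl, error_rate)
  if (nerr == 0) return(seqs)
  ri <- sample.int(n, nerr, replace = TRUE)
  pi <- sample.int(rl, nerr, replace = TRUE)
  for (k in seq_len(nerr)) {
    old <- substr(seqs[ri[k]], pi[k], pi[k])
    substr(seqs[ri[k]], pi[k], pi[k]) <-
      sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  seqs
}

#' Simulate one sample's aligned reads over a reference
#'
#' Builds the donor genome by applying the sample's events to the
#' reference, draws read (or fragment) start positions uniformly on the
#' donor at the requested coverage, and places each read back onto the
#' reference analytically: reads inside unbroken blocks get full-match
#' CIGARs; reads spanning an event junction are aligned to the block
#' holding the majority of their bases with the remainder soft-clipped.
#' Deletion junctions therefore produce `RIGHT_CLIP`s at the first deleted
#' base and `LEFT_CLIP`s at the first base after the deletion; tandem
#' duplications the mirrored pattern.
#'
#' @param reference A [Biostrings::DNAStringSet] (or FASTA path). Sequence
#'   bases are only consulted when `include_seq = TRUE`; placements are
#'   analytic.
#' @param events Data frame `type` (`"DEL"`/`"DUP"`), `start`, `end`
#'   (1-based inclusive affected bases), non-overlapping; `NULL` or empty
#'   for a normal sample.
#' @param coverage Haploid-genome fold coverage (x).
#' @param sam_path Output SAM path.
#' @param read_len Read length (default 100 bp).
#' @param paired Emit read pairs (default `TRUE`) with the given
#'   `inner_dist`; otherwise single-end.
#' @param error_rate Per-base substitution rate (default 0.001); only
#'   affects emitted bases, never placements or CIGARs.
#' @param inner_dist Inner mate distance in bp (default 500).
#' @param sample_id Read-group-style label used in read names.
#' @param include_seq Emit actual read bases with substitution errors
#'   (default `FALSE`: SEQ/QUAL are `*`, keeping large cohorts light).
#' @param fastq_path Optional path; when given (implies sequence
#'   emission), reads are also written as FASTQ for use with an external
#'   aligner (mates interleaved in paired mode).
#' @param seed Optional seed.
#' @param return_records Also return the emitted records as a data frame
#'   (`qname`, `flag`, `pos`, `cigar`) for oracle checks.
#' @return List with `sam` (path), `truth` (data frame `sample`, `type`,
#'   `left`, `right`), `n_reads`, and optionally `records`.
#' @export
sim_sample <- function(reference, events, coverage, sam_path,
                       read_len = 100, paired = TRUE, error_rate = 0.001,
                       inner_dist = 500, sample_id = "sample",
                       include_seq = FALSE, fastq_path = NULL,
                       seed = NULL, return_records = FALSE) {
  if (!is.null(fastq_path)) include_seq <- TRUE
  if (!is.null(seed)) set.seed(seed)
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  chrom <- sub("\\s.*$", "", names(reference)[1])
  ref_len <- Biostrings::width(reference)[1]
  blocks <- donor_blocks(events, ref_len)
  donor_len <- sum(blocks$ref_end - blocks$ref_start + 1)
  if (paired) {
    span <- 2L * read_len + inner_dist
    npair <- stats::rpois(1, coverage * donor_len / (2 * read_len))
    f <- sample.int(max(donor_len - span + 1L, 1L), npair, replace = TRUE)
    d <- c(f, f + read_len + inner_dist)
    qname <- rep(sprintf("%s_p%07d", sample_id, seq_len(npair)), 2)
    flag <- rep(c(99L, 147L), each = npair)
    mate <- c(npair + seq_len(npair), seq_len(npair))
  } else {
    nread <- stats::rpois(1, coverage * donor_len / read_len)
    d <- sample.int(max(donor_len - read_len + 1L, 1L), nread,
                    replace = TRUE)
    qname <- sprintf("%s_r%07d", sample_id, seq_len(nread))
    flag <- rep(0L, nread)
    mate <- NULL
  }
  rec <- map_donor_reads(d, read_len, blocks)
  rec$qname <- qname; rec$flag <- flag
  if (include_seq && length(d)) {
    donor <- paste(substring(as.character(reference[[1]]),
                             blocks$ref_start, blocks$ref_end),
                   collapse = "")
    seqs <- substring(donor, rec$dstart, rec$dstart + read_len - 1L)
    rec$seq <- inject_errors(seqs, error_rate)
  } else rec$seq <- "*"
  if (!is.null(mate)) {
    rec$rnext <- "="; rec$pnext <- rec$pos[mate]
    rec$tlen <- ifelse(rec$flag == 99L,
                       rec$pnext + read_len - rec$pos,
                       -(rec$pos + read_len - rec$pnext))
  } else {
    rec$rnext <- "*"; rec$pnext <- 0L; rec$tlen <- 0L
  }
  ord <- order(rec$pos)
  rec <- rec[ord, , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, ref_len))
  body <- paste(rec$qname, rec$flag, chrom, as.integer(rec$pos), 60L,
                rec$cigar, rec$rnext, as.integer(rec$pnext),
                as.integer(rec$tlen), rec$seq, "*", sep = "\t")
  writeLines(c(header, body), sam_path, useBytes = TRUE)
  if (!is.null(fastq_path)) {
    ord0 <- order(rec$qname)   # group mates together
    writeLines(paste0("@", rec$qname[ord0],
                      if (!is.null(mate))
                        ifelse(rec$flag[ord0] == 99L, "/1", "/2")
                      else "", "\n", rec$seq[ord0], "\n+\n",
                      strrep("I", read_len)),
               fastq_path, useBytes = TRUE)
  }
  truth <- if (!is.null(events) && nrow(events)) {
    data.frame(sample = sample_id, type = events$type,
               left = events$start, right = events$end,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample = character(), type = character(),
               left = numeric(), right = numeric(),
               stringsAsFactors = FALSE)
  }
  out <- list(sam = sam_path, truth = truth, n_reads = nrow(rec))
  if (return_records)
    out$records <- rec[c("qname", "flag", "pos", "cigar")]
  out
}

#' Simulate the full benchmark cohort
#'
#' Deterministic fan-out of [sim_sample()] over an event layout: each
#' configuration row is realized in `n_samples` samples at coverages
#' 1x..`n_samples`x. Writes one SAM per sample plus `truth.tsv`,
#' `truth.bed` (0-based half-open) and `manifest.tsv` into `dir`.
#'
#' @param reference A [Biostrings::DNAStringSet] or FASTA path.
#' @param layout Event layout, see [cohort_events()].
#' @param dir Output directory (created if needed).
#' @param paired,read_len,error_rate,inner_dist,include_seq Passed to
#'   [sim_sample()].
#' @param coverages Per-sample coverages within each configuration row
#'   (default `1:n_samples`, the benchmark's 1x..15x sweep).
#' @param seed Master seed; per-sample streams are derived from it.
#' @return List with `manifest` (data frame `sample`, `file`, `coverage`,
#'   `label`, `type`), `truth` (all carrier events) and `dir`.
#' @export
sim_cohort <- function(reference, layout = cohort_events(), dir,
                       paired = TRUE, read_len = 100, error_rate = 0.001,
                       inner_dist = 500, include_seq = FALSE,
                       coverages = NULL, seed = 1) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n_total <- sum(layout$n_samples)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  manifest <- list(); truth <- list(); k <- 0L
  for (i in seq_len(nrow(layout))) {
    ev <- if (layout$type[i] == "NORMAL") NULL else
      data.frame(type = layout$type[i], start = layout$start[i],
                 end = layout$end[i], stringsAsFactors = FALSE)
    for (j in seq_len(layout$n_samples[i])) {
      k <- k + 1L
      cov <- if (is.null(coverages)) j else coverages[j]
      sid <- sprintf("%s_%02dx", layout$label[i], cov)
      sam <- file.path(dir, paste0(sid, ".sam"))
      res <- sim_sample(reference, ev, coverage = cov, sam_path = sam,
                        read_len = read_len, paired = paired,
                        error_rate = error_rate, inner_dist = inner_dist,
                        sample_id = sid, include_seq = include_seq,
                        seed = sample_seeds[k])
      manifest[[k]] <- data.frame(
        sample = sid, file = sam, coverage = cov, label = layout$label[i],
        type = layout$type[i], stringsAsFactors = FALSE)
      if (nrow(res$truth)) truth[[length(truth) + 1L]] <- res$truth
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), type = character(), left = numeric(),
               right = numeric(), stringsAsFactors = FALSE)
  chrom <- sub("\\s.*$", "", names(reference)[1])
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = chrom, start = truth$left - 1L,
                    end = truth$right, name = truth$sample,
                    score = 0L, strand = ".", type = truth$type)
  utils::write.table(bed, file.path(dir, "truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  list(manifest = manifest, truth = truth, dir = dir)
}
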