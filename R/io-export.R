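## Plain-text import/export: count matrices, BED/bedGraph, per-sample
## reports, and a minimal symbolic-allele VCF.

#' Write / read a windowed matrix as tab-delimited text
#'
#' Windows are columns with `chrom:start-end` headers so segmentation can
#' be exercised without alignment files.
#'
#' @param mat Samples x windows matrix (row names = sample ids).
#' @param path Output (input) path.
#' @return `read_matrix_tsv` returns the matrix with a `windows` attribute
#'   (data frame `chrom`, `start`, `end`).
#' @export
write_matrix_tsv <- function(mat, path) {
  utils::write.table(as.data.frame(mat), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, row.names = 1)
  mat <- as.matrix(df)
  parts <- regmatches(colnames(mat),
                      regexec("^(.+):([0-9]+)-([0-9]+)$", colnames(mat)))
  windows <- data.frame(
    chrom = vapply(parts, `[`, "", 2),
    start = as.integer(vapply(parts, `[`, "", 3)),
    end = as.integer(vapply(parts, `[`, "", 4)))
  attr(mat, "windows") <- windows
  mat
}

#' Export carrier calls as BED (0-based half-open)
#'
#' One line per carrier sample per CNVR; the `name` field is
#' `sample|state|group`.
#'
#' @param result A [call_cohort()] / [kernbreak()] result.
#' @param path Output path.
#' @param chrom Chromosome name for the BED records.
#' @export
write_calls_bed <- function(result, path, chrom) {
  if (inherits(result, "kernbreak_result")) result <- result$calls
  calls <- result$calls
  bed <- data.frame(chrom = chrom, start = calls$left - 1,
                    end = calls$right,
                    name = paste(calls$sample, calls$state, calls$group,
                                 sep = "|"),
                    score = calls$support, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export the per-sample report as tab-delimited text
#'
#' @inheritParams write_calls_bed
#' @export
write_report_tsv <- function(result, path) {
  if (inherits(result, "kernbreak_result")) result <- result$calls
  utils::write.table(result$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export per-group calls as a minimal VCF with symbolic alleles
#'
#' One `<DEL>`/`<DUP>` record per called group with `END` and `CIPOS`
#' tags; carriers listed in the `SAMPLES` INFO field.
#'
#' @inheritParams write_calls_bed
#' @param radius Confidence interval half-width written as `CIPOS`
#'   (default 10).
#' @export
write_calls_vcf <- function(result, path, chrom, radius = 10) {
  if (inherits(result, "kernbreak_result")) result <- result$calls
  calls <- result$calls
  hdr <- c("##fileformat=VCFv4.2",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the variant\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
           "##INFO=<ID=SAMPLES,Number=.,Type=String,Description=\"Carrier samples\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  grp <- unique(calls[c("cnvr_id", "group", "state", "left", "right")])
  lines <- vapply(seq_len(nrow(grp)), function(i) {
    sel <- calls$cnvr_id == grp$cnvr_id[i] & calls$group == grp$group[i]
    sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;CIPOS=-%d,%d;SAMPLES=%s",
            chrom, as.integer(grp$left[i]),
            sprintf("cnvr%d_g%d", grp$cnvr_id[i], grp$group[i]),
            grp$state[i], grp$state[i], as.integer(grp$right[i]),
            radius, radius, paste(calls$sample[sel], collapse = ","))
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Export a kernel score profile as bedGraph
#'
#' @param positions Candidate positions (bp).
#' @param scores Scores at those positions.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_scores_bedgraph <- function(positions, scores, path, chrom) {
  utils::write.table(
    data.frame(chrom = chrom, start = as.integer(positions) - 1L,
               end = as.integer(positions), value = scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
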