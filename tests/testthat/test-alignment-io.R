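grid_t <- window_grid("chrT", 1, 100000, 500)

test_that("terminal soft-clips map to the specified junction records", {
  # 60M40S at p: right clip at p + 60; 40S60M at p: left clip at p;
  # 100M: no record
  sam <- write_test_sam(rbind(
    sam_record("r1", 1000, "60M40S"),
    sam_record("r2", 2000, "40S60M"),
    sam_record("r3", 3000, "100M")), tempfile(fileext = ".sam"))
  tab <- extract_splitreads(sam, grid_t, min_clip_len = 10)
  expect_equal(as.data.frame(tab),
               data.frame(pos = c(1060, 2000),
                          side = c("RIGHT_CLIP", "LEFT_CLIP"),
                          support = c(1L, 1L), stringsAsFactors = FALSE),
               ignore_attr = TRUE)
})

test_that("clip records aggregate support and honor min_clip_len", {
  sam <- write_test_sam(rbind(
    sam_record("a", 940, "60M40S"),
    sam_record("b", 980, "20M80S"),
    sam_record("c", 995, "5M95S"),     # same junction, different starts
    sam_record("d", 998, "2M98S"),     # 2M clip still >= 10 -> kept
    sam_record("e", 991, "9M5S"),      # clip 5 < min_clip_len -> dropped
    sam_record("f", 1000, "8S92M")), tempfile(fileext = ".sam"))
  tab <- extract_splitreads(sam, grid_t, min_clip_len = 10)
  expect_equal(tab$pos, 1000)
  expect_equal(tab$side, "RIGHT_CLIP")
  expect_equal(tab$support, 4L)
})

test_that("a read clipped on both ends yields records on both sides", {
  sam <- write_test_sam(sam_record("r", 5000, "20S60M20S"),
                        tempfile(fileext = ".sam"))
  tab <- extract_splitreads(sam, grid_t)
  expect_equal(tab$pos, c(5000, 5060))
  expect_equal(tab$side, c("LEFT_CLIP", "RIGHT_CLIP"))
})

test_that("splitread extraction is invariant to read order", {
  set.seed(4)
  recs <- sam_record(sprintf("r%d", 1:40),
                     sample(1000:2000, 40, replace = TRUE),
                     sample(c("100M", "50M50S", "30S70M"), 40,
                            replace = TRUE))
  s1 <- write_test_sam(recs, tempfile(fileext = ".sam"))
  s2 <- write_test_sam(recs[rev(seq_len(nrow(recs))), ],
                       tempfile(fileext = ".sam"))
  expect_equal(as.data.frame(extract_splitreads(s1, grid_t)),
               as.data.frame(extract_splitreads(s2, grid_t)),
               ignore_attr = TRUE)
})

test_that("window counts match an independent full-scan tally", {
  ref <- sim_reference(6e4, chrom = "chrT", seed = 9)
  sam <- tempfile(fileext = ".sam")
  sim_sample(ref, data.frame(type = "DEL", start = 20000, end = 30000),
             coverage = 4, sam_path = sam, paired = TRUE, seed = 10)
  g <- window_grid("chrT", 1, 6e4, 500)
  rc <- count_reads(sam, g)
  expect_equal(rc$counts, naive_window_tally(sam, g))
  expect_equal(sum(rc$counts), sum(naive_window_tally(sam, g)))
})

test_that("empty regions yield all-zero counts of correct length", {
  sam <- write_test_sam(sam_record("r", 90000, "100M"),
                        tempfile(fileext = ".sam"))
  g <- window_grid("chrT", 1, 10000, 500)
  expect_equal(count_reads(sam, g)$counts, rep(0L, 20))
})

test_that("duplicate-flagged reads are dropped only when requested", {
  sam <- write_test_sam(rbind(
    sam_record("r1", 1000, "100M"),
    sam_record("r1d", 1000, "100M", flag = 1024L),
    sam_record("r2", 1700, "100M")), tempfile(fileext = ".sam"))
  expect_equal(sum(count_reads(sam, grid_t, drop_duplicates = TRUE)$counts),
               2)
  expect_equal(sum(count_reads(sam, grid_t, drop_duplicates = FALSE)$counts),
               3)
})

test_that("mapping-quality and flag filters match the naive scan", {
  sam <- write_test_sam(rbind(
    sam_record("q0", 1000, "100M", mapq = 0L),
    sam_record("q20", 2000, "100M", mapq = 20L),
    sam_record("sec", 3000, "100M", flag = 256L),
    sam_record("sup", 4000, "100M", flag = 2048L),
    sam_record("un", 5000, "100M", flag = 4L)),
    tempfile(fileext = ".sam"))
  for (mq in c(0, 10, 30)) {
    expect_equal(count_reads(sam, grid_t, min_mapq = mq)$counts,
                 naive_window_tally(sam, grid_t, min_mapq = mq))
  }
})

test_that("missing chromosomes and indexes raise explicit errors", {
  sam <- write_test_sam(sam_record("r", 1000, "100M"),
                        tempfile(fileext = ".sam"))
  g_bad <- window_grid("chrZ", 1, 10000, 500)
  expect_error(count_reads(sam, g_bad), "chrZ")
  bam <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE)
  expect_error(count_reads(bam, grid_t), "index")
})

test_that("cigar reference widths agree with GenomicAlignments", {
  skip_if_not_installed("GenomicAlignments")
  cigs <- c("100M", "60M40S", "40S60M", "10S30M2D40M5S", "5H20M3I30M",
            "25M5N25M")
  expect_equal(unname(kernbreak:::cigar_features(cigs)[, 1]),
               GenomicAlignments::cigarWidthAlongReferenceSpace(cigs))
})

test_that("per-window GC fractions are exact on constructed sequences", {
  s <- Biostrings::DNAStringSet(paste0(
    strrep("A", 500), strrep("G", 500),
    strrep("ACGT", 125), strrep("N", 500)))
  names(s) <- "gcT"
  g <- window_grid("gcT", 1, 2000, 500)
  gc <- compute_gc_track(s, g)
  expect_equal(gc[1:3], c(0, 1, 0.5))
  expect_true(is.na(gc[4]))
  expect_error(compute_gc_track(s, window_grid("gcX", 1, 2000, 500)),
               "gcX")
})

test_that("interval tracks average onto windows by overlap", {
  g <- window_grid("chrT", 1, 2000, 500)
  f <- tempfile()
  writeLines(c("chrT\t0\t500\t1", "chrT\t500\t750\t0.4",
               "chrT\t750\t1000\t0.8"), f)
  v <- read_track_tsv(f, g)
  expect_equal(v[1:2], c(1, 0.6))
  expect_true(all(is.na(v[3:4])))
})
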