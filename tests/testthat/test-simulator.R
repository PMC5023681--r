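test_that("reference generation is deterministic and honors GC targets", {
  a <- sim_reference(1e4, seed = 51)
  b <- sim_reference(1e4, seed = 51)
  expect_equal(as.character(a), as.character(b))
  expect_equal(Biostrings::width(a), 1e4)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  sim_reference(1e4, seed = 51, fasta = f1)
  sim_reference(1e4, seed = 51, fasta = f2)
  expect_identical(readLines(f1), readLines(f2))
  # realized GC within 0.02 of a span's target (binomial at n = 20000)
  r <- sim_reference(5e4, seed = 52,
                     gc_profile = data.frame(start = 10001, end = 30000,
                                             gc = 0.6))
  g <- Biostrings::letterFrequency(
    Biostrings::subseq(r[[1]], 10001, 30000), "GC", as.prob = TRUE)
  expect_lt(abs(g - 0.6), 0.02)
  expect_error(sim_reference(5000), "10 kb")
})

test_that("donor genomes apply deletions and tandem duplications", {
  del <- kernbreak:::donor_blocks(
    data.frame(type = "DEL", start = 101, end = 200), 1000)
  expect_equal(del$ref_start, c(1, 201))
  expect_equal(del$ref_end, c(100, 1000))
  expect_equal(del$donor_start, c(1, 101))
  dup <- kernbreak:::donor_blocks(
    data.frame(type = "DUP", start = 101, end = 200), 1000)
  expect_equal(dup$ref_start, c(1, 101, 201))
  expect_equal(dup$ref_end, c(200, 200, 1000))
  expect_equal(dup$donor_start, c(1, 201, 301))
  expect_error(kernbreak:::donor_blocks(
    data.frame(type = "DEL", start = 1, end = 2000), 1000), "outside")
  expect_error(kernbreak:::donor_blocks(
    data.frame(type = c("DEL", "DUP"), start = c(100, 150),
               end = c(200, 400)), 1000), "non-overlapping")
})

test_that("junction reads carry the analytically expected CIGARs", {
  # deletion [201, 500]: a read with 60 donor bases before the junction
  # aligns 60M40S at junction - 60; the mirrored read aligns 40S60M at 501
  blocks <- kernbreak:::donor_blocks(
    data.frame(type = "DEL", start = 201, end = 500), 10000)
  rec <- kernbreak:::map_donor_reads(c(141, 181, 1, 300), 100, blocks)
  expect_equal(rec$pos, c(141, 501, 1, 600))
  expect_equal(rec$cigar, c("60M40S", "20S80M", "100M", "100M"))
})

test_that("event-free samples emit only full-match CIGARs", {
  ref <- sim_reference(2e4, seed = 53)
  sam <- tempfile(fileext = ".sam")
  res <- sim_sample(ref, NULL, coverage = 2, sam_path = sam,
                    paired = FALSE, seed = 54, return_records = TRUE)
  expect_true(all(res$records$cigar == "100M"))
  expect_equal(nrow(res$truth), 0)
})

test_that("read counts track coverage within sampling error", {
  ref <- sim_reference(5e4, seed = 55)
  for (paired in c(TRUE, FALSE)) {
    res <- sim_sample(ref, NULL, coverage = 8,
                      sam_path = tempfile(fileext = ".sam"),
                      paired = paired, seed = 56, return_records = TRUE)
    lambda <- 8 * 5e4 / 100
    expect_lt(abs(res$n_reads - lambda), 3 * sqrt(lambda) + 2)
  }
})

test_that("emitted junction clips sit exactly at the event junctions", {
  ref <- sim_reference(5e4, seed = 57)
  ev <- data.frame(type = c("DEL", "DUP"), start = c(10000, 30000),
                   end = c(15000, 35000))
  res <- sim_sample(ref, ev, coverage = 10,
                    sam_path = tempfile(fileext = ".sam"),
                    paired = TRUE, seed = 58, return_records = TRUE)
  r <- res$records
  right <- r[grepl("S$", r$cigar) & grepl("^[0-9]+M", r$cigar), ]
  f <- kernbreak:::cigar_features(right$cigar)
  # right clips at DEL left junction (10000) or DUP right junction (35001)
  expect_true(all((right$pos + f[, 1]) %in% c(10000, 35001)))
  left <- r[grepl("^[0-9]+S", r$cigar), ]
  expect_true(all(left$pos %in% c(15001, 30000)))
})

test_that("alignment readers reproduce the simulator's emissions exactly", {
  ref <- sim_reference(4e4, chrom = "chrT", seed = 59)
  grid <- window_grid("chrT", 1, 4e4, 500)
  sam <- tempfile(fileext = ".sam")
  res <- sim_sample(ref, data.frame(type = "DEL", start = 15000,
                                    end = 22000),
                    coverage = 5, sam_path = sam, paired = TRUE,
                    seed = 60, return_records = TRUE)
  rc <- count_reads(sam, grid)
  expect_equal(sum(rc$counts),
               sum(res$records$pos >= 1 & res$records$pos <= 4e4))
  expect_equal(rc$counts, naive_window_tally(sam, grid))
  tab <- extract_splitreads(sam, grid, min_clip_len = 10)
  expect_equal(as.data.frame(tab), naive_clip_scan(sam, grid, 10),
               ignore_attr = TRUE)
})

test_that("sequence emission respects the substitution error rate", {
  ref <- sim_reference(2e4, seed = 61)
  res <- sim_sample(ref, NULL, coverage = 3,
                    sam_path = tempfile(fileext = ".sam"), paired = FALSE,
                    error_rate = 0.01, include_seq = TRUE, seed = 62,
                    return_records = TRUE)
  sam <- readLines(res$sam)
  sam <- sam[!startsWith(sam, "@")]
  f <- strsplit(sam, "\t", fixed = TRUE)
  refc <- as.character(ref[[1]])
  mism <- vapply(f, function(x) {
    r <- substr(refc, as.integer(x[4]), as.integer(x[4]) + 99)
    sum(strsplit(x[10], "")[[1]] != strsplit(r, "")[[1]])
  }, numeric(1))
  n <- length(mism) * 100
  expect_lt(abs(sum(mism) - n * 0.01), 3 * sqrt(n * 0.01) + 3)
})

test_that("FASTQ emission writes every read with its bases", {
  ref <- sim_reference(2e4, seed = 65)
  fq <- tempfile(fileext = ".fq")
  res <- sim_sample(ref, NULL, coverage = 1,
                    sam_path = tempfile(fileext = ".sam"), paired = TRUE,
                    fastq_path = fq, seed = 66)
  lines <- readLines(fq)
  expect_equal(length(lines), 4 * res$n_reads)
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
  expect_true(all(nchar(lines[seq(2, length(lines), 4)]) == 100))
  # mates are distinguishable
  expect_equal(sum(grepl("/1$", lines[seq(1, length(lines), 4)])),
               res$n_reads / 2)
})

test_that("the cohort fan-out writes one SAM and truth row per carrier", {
  ref <- sim_reference(2e4, seed = 63)
  layout <- data.frame(label = c("d", "n"), type = c("DEL", "NORMAL"),
                     start = c(5000, NA), end = c(9000, NA),
                     n_samples = 3)
  dir <- tempfile()
  coh <- sim_cohort(ref, layout, dir = dir, paired = FALSE, seed = 64)
  expect_equal(nrow(coh$manifest), 6)
  expect_equal(coh$manifest$coverage, rep(1:3, 2))
  expect_equal(nrow(coh$truth), 3)
  expect_true(all(file.exists(coh$manifest$file)))
  expect_true(file.exists(file.path(dir, "truth.bed")))
  # deterministic under the master seed
  dir2 <- tempfile()
  coh2 <- sim_cohort(ref, layout, dir = dir2, paired = FALSE, seed = 64)
  expect_identical(readLines(coh$manifest$file[2]),
                   readLines(coh2$manifest$file[2]))
  # explicit per-row coverage assignment
  coh3 <- sim_cohort(ref, layout, dir = tempfile(), paired = FALSE,
                     coverages = c(4, 5, 6), seed = 64)
  expect_equal(coh3$manifest$coverage, rep(4:6, 2))
})

test_that("the benchmark layout realizes 120 samples over 1-15x", {
  layout <- cohort_events()
  expect_equal(sum(layout$n_samples), 120)
  expect_equal(nrow(layout), 8)
  expect_equal(layout$n_samples, rep(15, 8))
  expect_equal(sort(unique(layout$type)), c("DEL", "DUP", "NORMAL"))
  expect_equal(cohort_focus(layout), c(445220 - 5000, 530000 + 5000))
})
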