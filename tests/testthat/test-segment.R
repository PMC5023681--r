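test_that("flat signals give one segment, noiseless steps exact cuts", {
  s <- segment_sample(rep(0, 120))
  expect_equal(s$changepoints, integer(0))
  expect_equal(s$means, 0)
  s <- segment_sample(c(rep(0, 50), rep(-1, 20), rep(0, 50)))
  expect_equal(s$changepoints, c(51L, 71L))
  expect_equal(s$means, c(0, -1, 0))
  expect_equal(s$fitted, c(rep(0, 50), rep(-1, 20), rep(0, 50)))
})

test_that("degenerate signals are rejected", {
  expect_error(segment_sample(numeric(0)), "empty")
  expect_error(segment_sample(c(NA, NA)), "empty|missing")
  expect_error(segment_sample(c(1, NA, 2)), "missing")
})

test_that("noisy steps are recovered within one window almost always", {
  set.seed(11)
  hits <- 0L
  for (r in 1:100) {
    x <- c(rnorm(50, 0, 0.1), rnorm(20, -0.5, 0.1), rnorm(50, 0, 0.1))
    cp <- segment_sample(x)$changepoints
    ok <- length(cp) >= 2 && min(abs(cp - 51)) <= 1 &&
      min(abs(cp - 71)) <= 1
    hits <- hits + ok
  }
  expect_gte(hits, 95)
})

test_that("short events inside long flat signals are detectable", {
  # the joint two-change-point scan must find a 3-window dip in 600
  set.seed(12)
  x <- rnorm(600, 0, 0.1)
  x[301:303] <- x[301:303] - 1
  cp <- segment_sample(x)$changepoints
  expect_true(all(c(301L, 304L) %in% cp))
})

test_that("segment means evaluated on sub-regions reproduce window fits", {
  set.seed(13)
  grid <- window_grid("c", 1, 50000, 500)
  sigs <- list(c(rep(0, 40), rep(1, 30), rep(0, 30)),
               c(rep(0, 20), rep(-1, 50), rep(0, 30)),
               rep(0, 100))
  segs <- lapply(sigs, segment_sample)
  part <- build_partition(segs, grid)
  sm <- seg_matrix(segs, part, grid, c("a", "b", "c"))
  # round-trip: each sub-region value equals the sample's fitted value on
  # every window the sub-region covers
  for (i in seq_along(segs)) {
    for (r in seq_len(nrow(part$sub_regions))) {
      w1 <- kernbreak:::window_index(grid, part$sub_regions$start[r])
      w2 <- kernbreak:::window_index(grid, part$sub_regions$end[r])
      expect_equal(unname(rep(sm$values[i, r], w2 - w1 + 1)),
                   segs[[i]]$fitted[w1:w2])
    }
  }
})

test_that("partition boundaries are the deduplicated union of change-points", {
  grid <- window_grid("c", 1, 5000, 500)
  seg_at <- function(cp) structure(
    list(changepoints = cp, means = 0, fitted = rep(0, 10)),
    class = "segmentation")
  one <- build_partition(list(seg_at(4L)), grid)
  expect_equal(nrow(one$sub_regions), 2)
  two <- build_partition(list(seg_at(c(3L, 7L)), seg_at(c(4L, 7L, 9L))),
                         grid)
  expect_equal(two$boundaries, c(1, 1001, 1501, 3001, 4001, 5001))
  # order-invariance and idempotence over samples
  rev2 <- build_partition(list(seg_at(c(4L, 7L, 9L)), seg_at(c(3L, 7L))),
                          grid)
  expect_equal(two, rev2)
  same <- build_partition(list(seg_at(c(3L, 7L)), seg_at(c(3L, 7L))), grid)
  expect_equal(same, build_partition(list(seg_at(c(3L, 7L))), grid))
})

test_that("CNVR calling applies thresholds, merging and carrier counts", {
  grid <- window_grid("c", 1, 20000, 500)
  segs <- lapply(1:10, function(i) {
    v <- rep(0, 40)
    if (i == 1) v[9:14] <- -0.6
    segment_sample(v)
  })
  part <- build_partition(segs, grid)
  sm <- seg_matrix(segs, part, grid, as.character(1:10))
  cn <- call_cnvrs(sm)
  expect_equal(nrow(cn$cnvrs), 1)
  expect_equal(cn$cnvrs$start, 4001)
  expect_equal(cn$cnvrs$end, 7000)
  expect_equal(cn$cnvrs$carrier_count, 1)
  expect_equal(sum(cn$states == "DEL"), 1)
  # count_threshold 2 drops the single-carrier call
  expect_equal(nrow(call_cnvrs(sm, count_threshold = 2)$cnvrs), 0)
  # values within (-0.25, 0.25) produce no calls
  flat <- lapply(1:4, function(i) segment_sample(runif(40, -0.2, 0.2)))
  smf <- seg_matrix(flat, build_partition(flat, grid), grid,
                    as.character(1:4))
  expect_equal(nrow(call_cnvrs(smf)$cnvrs), 0)
  expect_error(call_cnvrs(sm, dup_threshold = -1), "thresholds")
})

test_that("raising thresholds never creates new variant sub-regions", {
  set.seed(14)
  grid <- window_grid("c", 1, 10000, 500)
  segs <- lapply(1:6, function(i)
    segment_sample(rnorm(20, 0, 0.4)))
  sm <- seg_matrix(segs, build_partition(segs, grid), grid,
                   as.character(1:6))
  for (thr in c(0.2, 0.25, 0.35, 0.5)) {
    lo <- call_cnvrs(sm, dup_threshold = thr, del_threshold = -thr)
    hi <- call_cnvrs(sm, dup_threshold = thr + 0.1,
                     del_threshold = -thr - 0.1)
    expect_true(all(which(hi$states == "DUP") %in%
                    which(lo$states == "DUP")))
    expect_true(all(which(hi$states == "DEL") %in%
                    which(lo$states == "DEL")))
  }
})
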