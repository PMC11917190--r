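test_that("load_counts round-trips simulator output exactly", {
  fx <- small_fixture(seed = 8, genome_length = 3e5)
  prof <- suppressMessages(load_counts(fx$sim$counts[[1]], fx$fmap))
  # per valid fragment, the loaded raw count equals the emitted count of its
  # NlaIII end
  ends <- fx$sim$ends
  cnt <- fx$sim$counts[[1]]$count
  vrows <- which(fx$fmap$valid)
  expected <- vapply(vrows, function(v) sum(cnt[ends$frag == v]), numeric(1))
  expect_equal(prof$raw, expected)
  expect_equal(length(prof$raw), sum(fx$fmap$valid))
})

test_that("load_counts drops records in invalid fragments and logs them", {
  fx <- small_fixture(seed = 9, genome_length = 2e5)
  blind <- which(!fx$fmap$valid & fx$fmap$length > 10)[1L]
  rec <- data.frame(chrom = attr(fx$fmap, "chrom"),
                    start = fx$fmap$start[blind],
                    end = fx$fmap$start[blind] + 5, count = 3)
  valid1 <- which(fx$fmap$valid)[1L]
  ok <- data.frame(chrom = attr(fx$fmap, "chrom"),
                   start = fx$fmap$start[valid1],
                   end = fx$fmap$start[valid1] + 5, count = 2)
  expect_message(prof <- load_counts(rbind(rec, ok), fx$fmap), "dropped")
  expect_equal(prof$n_dropped, 1L)
  expect_equal(sum(prof$raw), 2)
  # all records unassignable -> error
  expect_error(suppressMessages(load_counts(rec, fx$fmap)), "assignable")
})

test_that("load_counts rejects empty and malformed files", {
  f <- tempfile()
  writeLines(character(0), f)
  fx <- small_fixture(seed = 9, genome_length = 2e5)
  expect_error(load_counts(f, fx$fmap), "empty")
  writeLines(c("chrS\t0\t10\t5", "chrS\tfoo\t20\t1"), f)
  expect_error(read_bedgraph(f), "line 2")
  unlink(f)
})

test_that("normalization scales to the target and is scale-invariant", {
  fx <- small_fixture(seed = 10, genome_length = 2e5)
  prof <- suppressMessages(load_counts(fx$sim$counts[[1]], fx$fmap))

  p2 <- prof
  p2$raw <- rep(2, length(prof$raw))
  n2 <- normalize_profile(p2, target_total = 1e6)
  expect_equal(n2$normalized, rep(1e6 / length(p2$raw), length(p2$raw)))

  p13 <- prof
  p13$raw <- c(1, 3, rep(0, length(prof$raw) - 2))
  expect_equal(normalize_profile(p13, target_total = 100)$normalized[1:2],
               c(25, 75))

  a <- normalize_profile(prof)
  pk <- prof
  pk$raw <- prof$raw * 7.5
  b <- normalize_profile(pk)
  expect_equal(a$normalized, b$normalized)
  expect_equal(sum(a$normalized), 1e6)

  pz <- prof
  pz$raw <- rep(0, length(prof$raw))
  expect_error(normalize_profile(pz), "all-zero")
})

test_that("smoothing is a centered running mean with symmetric edge shrink", {
  fx <- small_fixture(seed = 11, genome_length = 3e5)
  prof <- suppressMessages(load_counts(fx$sim$counts[[1]], fx$fmap))
  n <- length(prof$raw)

  # constant profile is a fixed point
  pc <- prof
  pc$raw <- rep(4, n)
  sc <- smooth_profile(normalize_profile(pc), window = 30)
  expect_equal(sc$smoothed, rep(sc$normalized[1], n))

  # single interior spike: max smoothed value is h/30 at full windows
  ps <- prof
  ps$raw <- rep(0, n)
  ps$raw[floor(n / 2)] <- 60
  ps <- normalize_profile(ps, target_total = 60)  # normalized == raw
  ss <- smooth_profile(ps, window = 30)
  expect_equal(max(ss$smoothed), 60 / 30)

  # interior values agree with a direct convolution oracle (15 left, 14 right)
  pr <- smooth_profile(normalize_profile(prof), window = 30)
  for (i in c(20, 50, floor(n / 2))) {
    expect_equal(pr$smoothed[i], mean(pr$normalized[(i - 15):(i + 14)]))
  }
  # translation equivariance along the fragment index
  sh <- 5L
  p_shift <- prof
  p_shift$raw <- c(prof$raw[-seq_len(sh)], prof$raw[seq_len(sh)])
  sm_shift <- smooth_profile(normalize_profile(p_shift), window = 30)$smoothed
  mid <- 40:(n - 40)
  expect_equal(sm_shift[mid], pr$smoothed[mid + sh])

  expect_error(smooth_profile(normalize_profile(prof), window = n + 1),
               "at least")
  expect_error(smooth_profile(prof), "normalized")
})

test_that("bin_counts assigns ends to 5 kb bins over the +/-1 Mb window", {
  fx <- small_fixture(seed = 12, genome_length = 3e5)
  prof <- suppressMessages(load_counts(fx$sim$counts[[1]], fx$fmap))
  vp <- prof$viewpoint

  b <- bin_counts(normalize_profile(prof), bin = 5000, span = 1e6)
  expect_equal(nrow(b), 400L)
  expect_equal(b$start[1], vp - 1e6)
  expect_equal(b$end[400], vp + 1e6)
  # conservation: bin totals equal the summed counts of in-window midpoints
  pn <- normalize_profile(prof)
  inwin <- pn$pos >= vp - 1e6 & pn$pos < vp + 1e6
  expect_equal(sum(b$count), sum(pn$normalized[inwin]))

  # a single end with count 7 at viewpoint + 2500 lands in the first
  # right-side bin
  p1 <- prof
  p1$raw <- rep(0, length(prof$raw))
  i <- which.min(abs(prof$pos - (vp + 2500)))
  p1$raw[i] <- 7
  p1$normalized <- p1$raw
  b1 <- bin_counts(p1, use = "normalized")
  ibin <- floor((prof$pos[i] - (vp - 1e6)) / 5000) + 1
  expect_equal(b1$count[ibin], 7)
  expect_equal(sum(b1$count), 7)

  expect_error(bin_counts(pn, bin = 3000, span = 1e6), "multiple")
})

test_that("replicate correlation behaves at its extremes and on NB replicates", {
  fx <- small_fixture(seed = 13, genome_length = 4e5)
  p1 <- suppressMessages(prepare_profile(fx$sim$counts[[1]], fx$fmap, "rep1"))
  p2 <- suppressMessages(prepare_profile(fx$sim$counts[[2]], fx$fmap, "rep2"))
  b1 <- bin_counts(p1)
  b2 <- bin_counts(p2)
  expect_equal(replicate_correlation(b1, b1)$r, 1)
  # anticorrelated contrivance
  bneg <- b1
  bneg$count <- max(b1$count) - b1$count
  expect_equal(replicate_correlation(b1, bneg)$r, -1)
  # simulator replicates at amplitude >= 100 correlate strongly
  expect_gt(replicate_correlation(b1, b2)$r, 0.8)
  # zero variance is reported as undefined
  bz <- b1
  bz$count <- rep(1, nrow(b1))
  expect_warning(rz <- replicate_correlation(bz, b2), "variance")
  expect_true(is.na(rz$r))
})
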