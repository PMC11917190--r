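test_that("PAVA solves the textbook cases", {
  # already non-increasing input is a fixed point
  y <- c(9, 7, 7, 3, 1)
  expect_equal(pava_nonincreasing(y), y)
  # the canonical pooling example
  expect_equal(pava_nonincreasing(c(3, 1, 2)), c(3, 1.5, 1.5))
  # constant input
  expect_equal(pava_nonincreasing(rep(2, 6)), rep(2, 6))
  # weighted pooling: block value is the weighted mean
  expect_equal(pava_nonincreasing(c(1, 3), w = c(1, 3)), c(2.5, 2.5))
  expect_error(pava_nonincreasing(c(1, 2), w = c(1, -1)), "positive")
})

test_that("PAVA equals the exhaustive block-partition oracle and isoreg", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    y <- round(rnorm(n, sd = 3), 2)
    fit <- pava_nonincreasing(y)
    expect_equal(fit, oracle_isotonic_nonincreasing(y), tolerance = 1e-9)
    # independent cross-check: stats::isoreg fits non-decreasing sequences
    expect_equal(fit, rev(stats::isoreg(rev(y))$yf), tolerance = 1e-9)
    # feasibility
    expect_true(all(diff(fit) <= 1e-12))
  }
})

test_that("background fit is non-increasing per arm with nonnegative values", {
  fx <- small_fixture(seed = 20, genome_length = 4e5)
  profs <- suppressMessages(lapply(fx$sim$counts, prepare_profile, fmap = fx$fmap))
  ms <- rowMeans(sapply(profs, `[[`, "smoothed"))
  d <- profs[[1]]$distance
  fit <- fit_monotonic_background(ms, d, flank = 1e6)
  for (a in c("up", "down")) {
    sel <- which(fit$arm == a & fit$in_flank)
    ord <- sel[order(abs(d[sel]))]
    expect_true(all(diff(fit$b[ord]) <= 1e-9))
  }
  expect_true(all(fit$b[fit$in_flank] >= 0))
  # input already non-increasing in |distance|: fit equals input
  dd2 <- c(-(30:1), 1:30) * 1000
  vals2 <- 31 - abs(dd2) / 1000
  fit2 <- fit_monotonic_background(vals2, dd2, flank = 1e6, min_points = 5)
  expect_equal(fit2$b, vals2)
  # constant input: fit equals the constant, linear sigma = 0
  const <- rep(5, 60)
  dd <- c(-(30:1), 1:30) * 1000
  fitc <- fit_monotonic_background(const, dd, min_points = 5)
  expect_equal(fitc$b, const)
  expect_equal(unname(fitc$sigma), c(0, 0))
  expect_error(fit_monotonic_background(1:5, c(-1, -2, 1, 2, 3) * 1e3),
               "at least")
})

test_that("local coverage score counts nonzero fractions in the window", {
  x <- rep(1, 50)
  expect_equal(local_coverage_score(x, index = 25), 1)
  expect_equal(local_coverage_score(rep(0, 50), index = 25), 0)
  y <- rep(0, 60)
  y[16:27] <- 2  # 12 nonzero of the 30-fragment window around index 30
  expect_equal(local_coverage_score(y, index = 30), 0.4)
  expect_error(local_coverage_score(rep(1, 10), window = 30), "window")
})

test_that("criterion 1 requires the signal in every replicate", {
  fx <- small_fixture(seed = 21, genome_length = 4e5)
  profs <- suppressMessages(lapply(seq_along(fx$sim$counts), function(r) {
    prepare_profile(fx$sim$counts[[r]], fx$fmap, replicate = paste0("rep", r))
  }))
  # inflate a block of fragments in replicate 1 only, far from the viewpoint
  n <- length(profs[[1]]$raw)
  idx <- which(abs(profs[[1]]$distance) > 5e4)[1:15]
  p1 <- profs[[1]]
  p1$raw[idx] <- p1$raw[idx] + 500
  p1 <- smooth_profile(normalize_profile(p1), window = 30)
  cl <- call_fragments(list(p1, profs[[2]]))
  up_rep1_only <- idx[cl$crit_snr[idx] & cl$crit_viewpoint_fraction[idx] &
                        !cl$crit_replicates[idx]]
  # fragments exceeding the background in replicate 1 only are never called
  expect_false(any(cl$significant[up_rep1_only]))
  expect_error(call_fragments(profs[1]), "at least two")
})

test_that("raising the SNR threshold never enlarges the called set", {
  r <- run_sim_call(31, three_planted())
  called3 <- which(r$calls$significant)
  cl4 <- call_fragments(r$profiles, config = caller_config(snr_k = 4))
  cl5 <- call_fragments(r$profiles, config = caller_config(snr_k = 5))
  expect_true(all(which(cl4$significant) %in% called3))
  expect_true(all(which(cl5$significant) %in% which(cl4$significant)))
})

test_that("merging respects the 40 bp boundary and matches the closure oracle", {
  frags <- data.frame(chrom = "chrS",
                      start = c(100, 240, 400), end = c(200, 360, 500))
  # gaps: 40 (merged) and 40 (merged)
  expect_equal(length(merge_to_pcres(frags, merge_gap = 40)), 1L)
  frags2 <- data.frame(chrom = "chrS", start = c(100, 241), end = c(200, 300))
  expect_equal(length(merge_to_pcres(frags2, merge_gap = 40)), 2L)
  # single fragment -> single spanning pCRE
  one <- merge_to_pcres(data.frame(chrom = "chrS", start = 10, end = 60))
  expect_equal(GenomicRanges::start(one), 11)
  expect_equal(GenomicRanges::end(one), 60)

  set.seed(43)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    s <- sort(sample.int(2000, n))
    e <- s + sample.int(60, n, replace = TRUE)
    # drop overlapping fragments to mimic a fragment map
    keep <- c(TRUE, s[-1] >= cummax(e)[-n])
    df <- data.frame(chrom = "chrS", start = s[keep], end = e[keep])
    got <- merge_to_pcres(df, merge_gap = 40)
    want <- oracle_merge(df$start, df$end, 40)
    expect_equal(GenomicRanges::start(got) - 1L, unname(want[, 1]))
    expect_equal(GenomicRanges::end(got), unname(want[, 2]))
  }
})

test_that("planted interactions are recovered and appear in the audit trail", {
  r <- run_sim_call(32, list(list(center = 1.15e6, half_width = 10, fold = 8)))
  tr <- r$truth$planted_regions
  mid <- (r$calls$start + r$calls$end) / 2
  inp <- mid >= tr$start[1] & mid < tr$end[1]
  # >= 80% of planted fragments called for a fold-8 interaction
  expect_gte(mean(r$calls$significant[inp]), 0.8)
  # per-criterion columns are present for auditing
  expect_true(all(c("crit_replicates", "crit_viewpoint_fraction",
                    "crit_snr", "crit_coverage") %in% names(r$calls)))
  ev <- evaluate_recovery(r$pcres, r$truth,
                          margin = smoothing_margin(r$fmap))
  expect_equal(ev$sensitivity, 1)
})
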