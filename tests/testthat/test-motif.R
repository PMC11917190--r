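test_that("count_oligos counts both strands in canonical form", {
  # one duplex window seen from both strands counts 2
  cts <- count_oligos("AAAAAA", 6)
  expect_equal(unname(cts[["AAAAAA"]]), 2)
  expect_equal(sum(cts), 2)
  expect_equal(attr(cts, "n_positions"), 2)

  # brute-force two-strand scan oracle on a random sequence
  set.seed(81)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  for (k in c(6, 7)) {
    cts <- count_oligos(s, k)
    want <- table(c(
      vapply(seq_len(300 - k + 1), function(i) substring(s, i, i + k - 1), ""),
      vapply(seq_len(300 - k + 1), function(i) substring(rc, i, i + k - 1), "")
    ))
    canon <- ifelse(names(want) <= chartr("ACGT", "TGCA", sapply(
      strsplit(names(want), ""), function(x) paste(rev(x), collapse = ""))),
      names(want), NA)
    # collapse the oracle table to canonical form
    rcn <- vapply(names(want), function(w) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1]]), collapse = "")
    }, "")
    cn <- ifelse(names(want) <= rcn, names(want), rcn)
    oracle <- tapply(as.numeric(want), cn, sum)
    got <- cts[names(oracle)]
    expect_equal(as.numeric(got), as.numeric(oracle))
    expect_equal(sum(cts), 2 * (300 - k + 1))
  }

  # strand symmetry: a sequence and its reverse complement count identically
  expect_equal(as.numeric(count_oligos(s, 6)),
               as.numeric(count_oligos(rc, 6)))

  # empty input and too-short input
  expect_equal(sum(count_oligos(character(0), 6)), 0)
  expect_warning(z <- count_oligos("ACG", 6), "shorter")
  expect_equal(sum(z), 0)
  # windows containing N are skipped
  expect_equal(attr(count_oligos("AAAAANAAAAA", 6), "n_positions"), 0)
})

test_that("oligo enrichment is null-behaved at expectation", {
  # with uniform background, a count exactly at expectation is unremarkable
  set.seed(82)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  enr <- oligo_enrichment(count_oligos(s, 6),
                          background = c(A = .25, C = .25, G = .25, T = .25))
  at_exp <- enr[abs(enr$observed - enr$expected) < 0.5, ]
  if (nrow(at_exp)) {
    expect_true(all(at_exp$p > 0.3))
    expect_true(all(at_exp$evalue >= 1))
  }
  expect_true(all(enr$evalue >= enr$p))
  expect_true(all(diff(enr$evalue) >= -1e-12))
})

test_that("a planted 6-mer in uniform background is strongly enriched", {
  set.seed(83)
  chars <- sample(c("A", "C", "G", "T"), 2000, TRUE)
  at <- round(seq(40, 1980, length.out = 20))
  for (p in at) chars[p:(p + 5)] <- c("G", "T", "A", "C", "G", "T")[1:6]
  s <- paste(chars, collapse = "")
  cts <- count_oligos(s, 6)
  enr <- oligo_enrichment(cts, background = c(A = .25, C = .25, G = .25, T = .25))
  top <- enr[1, ]
  expect_equal(top$oligo, min("GTACGT", "ACGTAC"))
  expect_lt(top$evalue, 1e-6)
  # the p-value matches an exact binomial-tail oracle on duplex occurrences
  q <- 2 * 0.25^6
  n_dup <- attr(cts, "n_positions") / 2
  want <- oracle_binom_tail(ceiling(top$observed / 2), n_dup, q)
  expect_equal(top$p, want, tolerance = 1e-10)
  # all flagged oligos match the oracle
  flagged <- enr[enr$evalue < 1, ]
  for (i in seq_len(nrow(flagged))) {
    rcw <- paste(rev(strsplit(chartr("ACGT", "TGCA", flagged$oligo[i]),
                              "")[[1]]), collapse = "")
    qq <- if (rcw == flagged$oligo[i]) 0.25^6 else 2 * 0.25^6
    expect_equal(flagged$p[i],
                 oracle_binom_tail(ceiling(flagged$observed[i] / 2), n_dup, qq),
                 tolerance = 1e-10)
  }
  expect_error(oligo_enrichment(cts, background = c(A = .5, C = .5, G = 0, T = 0)),
               "degenerate")
})

test_that("E-values are calibrated on uniform input", {
  # expected number of false E < 1 hits is about one or fewer per run
  set.seed(84)
  hits <- vapply(1:15, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
    enr <- oligo_enrichment(count_oligos(s, 6),
                            background = c(A = .25, C = .25, G = .25, T = .25))
    sum(enr$evalue < 1)
  }, numeric(1))
  expect_lte(mean(hits), 1.5)
})

test_that("greedy assembly merges overlapping oligos in both orientations", {
  # the worked overlap-5 example gives one matrix of width 7
  m <- assemble_matrices(c("ACGTAC", "CGTACG"), weights = c(3, 2))
  expect_equal(length(m), 1L)
  expect_equal(ncol(m[[1]]$mat), 7L)
  expect_setequal(m[[1]]$members, c("ACGTAC", "CGTACG"))
  # column counts add where the oligos overlap
  expect_equal(unname(colSums(m[[1]]$mat)), c(3, 5, 5, 5, 5, 5, 2))

  # a single oligo becomes a width-k matrix carrying its counts
  one <- assemble_matrices("TTTAAA", weights = 4)
  expect_equal(length(one), 1L)
  expect_equal(ncol(one[[1]]$mat), 6L)
  expect_equal(unname(colSums(one[[1]]$mat)), rep(4, 6))
  expect_equal(unname(one[[1]]$mat["T", 1]), 4)

  # disjoint oligos stay separate
  disj <- assemble_matrices(c("AAAAAA", "CCCCCC"))
  expect_equal(length(disj), 2L)

  # reverse-complement overlaps are found
  rcm <- assemble_matrices(c("ACGTAA", "CCTTAC"))  # rc(CCTTAC) = GTAAGG
  expect_equal(length(rcm), 1L)
  expect_equal(ncol(rcm[[1]]$mat), 8L)
})

test_that("motif matrices serialize to MEME and TRANSFAC formats", {
  mats <- assemble_matrices(c("ACGTAC", "CGTACG"), weights = c(3, 2))
  meme <- tempfile(fileext = ".meme")
  write_meme(mats, meme)
  lines <- readLines(meme)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^MOTIF", lines)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 7", lines)))
  tf <- tempfile(fileext = ".transfac")
  write_transfac(mats, tf)
  expect_true(any(grepl("^P0", readLines(tf))))
  unlink(c(meme, tf))
})
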