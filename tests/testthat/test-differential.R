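gr <- function(starts, ends, chrom = "chrS") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = starts + 1, end = ends))
}

test_that("classification handles the toy and degenerate configurations", {
  # toy from first principles: expressing {[100,200),[500,600)},
  # baseline1 {[150,250)}, baseline2 {[800,900)}
  # [150,250) overlaps the expressing [100,200): present in both conditions,
  # so it contributes the shared call and is not lost; only [800,900) is lost
  cls <- classify_pcres(gr(c(100, 500), c(200, 600)),
                        list(gr(150, 250), gr(800, 900)))
  expect_equal(unname(cls$counts), c(1L, 1L, 1L))
  expect_equal(cls$total, 3L)

  # identical sets: all shared, nothing gained or lost
  e <- gr(c(0, 1000), c(100, 1100))
  cls2 <- classify_pcres(e, list(e, e))
  expect_equal(unname(cls2$counts), c(2L, 0L, 0L))

  # disjoint sets: everything gained, each merged baseline region lost
  cls3 <- classify_pcres(gr(0, 100), list(gr(500, 600), gr(550, 700)))
  expect_equal(unname(cls3$counts), c(0L, 1L, 1L))

  expect_error(classify_pcres(GenomicRanges::GRanges(),
                              list(GenomicRanges::GRanges())), "empty")
})

test_that("classification is a partition matching the brute-force oracle", {
  set.seed(51)
  for (i in 1:40) {
    e <- random_granges(sample(0:12, 1), 5e4)
    b1 <- random_granges(sample(0:12, 1), 5e4)
    b2 <- random_granges(sample(1:12, 1), 5e4)
    if (length(e) == 0 && length(b1) == 0 && length(b2) == 0) next
    cls <- classify_pcres(e, list(b1, b2))
    as_df <- function(g) data.frame(start = GenomicRanges::start(g) - 1,
                                    end = GenomicRanges::end(g))
    want <- oracle_classify(as_df(e), list(as_df(b1), as_df(b2)))
    expect_equal(cls$counts, want)
    # shared + gained + lost partitions the distinct merged regions
    expect_equal(cls$total, sum(want))
    expect_equal(length(cls$regions), cls$total)
    # invariant under baseline reordering
    cls_r <- classify_pcres(e, list(b2, b1))
    expect_equal(cls_r$counts, cls$counts)
  }
})

test_that("distance classes use the documented boundaries", {
  expect_equal(as.character(distance_class(0)), "near")
  expect_equal(as.character(distance_class(199999)), "near")
  expect_equal(as.character(distance_class(200000)), "medium")
  expect_equal(as.character(distance_class(500000)), "medium")
  expect_equal(as.character(distance_class(500001)), "far")
  expect_equal(as.character(distance_class(750000)), "far")

  g <- gr(c(1e6, 2e6), c(1e6 + 10, 2e6 + 10))
  expect_equal(as.character(distance_class(g, viewpoint = 1e6)),
               c("near", "far"))
  expect_error(distance_class(gr(0, 10, chrom = "chr2"), viewpoint = 0,
                              viewpoint_chrom = "chrS"), "cis")
})

test_that("distance densities integrate to one and match a kernel-sum oracle", {
  regions <- gr(seq(0, 19) * 5000, seq(0, 19) * 5000 + 800)
  regions$class <- rep(c("shared", "gained"), each = 10)
  dens <- distance_density(regions, viewpoint = 0)
  expect_setequal(names(dens), c("shared", "gained"))
  for (d in dens) {
    area <- sum(d$y) * mean(diff(d$x))
    expect_lt(abs(area - 1), 1e-3)
  }
  # values match the direct Gaussian kernel sum at the evaluation grid
  mid <- floor((GenomicRanges::start(regions) - 1 + GenomicRanges::end(regions)) / 2)
  x <- abs(mid - 0)[regions$class == "shared"]
  d1 <- dens[["shared"]]
  oracle <- vapply(d1$x[c(10, 100, 300)], function(g) {
    mean(stats::dnorm((g - x) / d1$bw)) / d1$bw
  }, numeric(1))
  expect_equal(d1$y[c(10, 100, 300)], oracle, tolerance = 1e-2)
  # an all-same-distance class peaks at that distance
  same <- gr(rep(10000, 3), rep(10300, 3))
  same$class <- "lost"
  dlost <- suppressWarnings(distance_density(same, viewpoint = 0))
  expect_lt(abs(dlost$lost$x[which.max(dlost$lost$y)] - 10150), 500)
  # singleton class dropped with warning
  single <- gr(c(0, 100, 5000), c(50, 150, 5100))
  single$class <- c("shared", "shared", "gained")
  expect_warning(distance_density(single, viewpoint = 0), "gained")
})

test_that("promoter annotation follows strand-aware windows and precedence", {
  genes <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(start = c(10001, 30001),
                                                   end = c(15000, 35000)),
                                  strand = c("+", "-"))
  exons <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(start = 12001, end = 12500))
  # pCRE overlapping TSS-500 of the + strand gene
  expect_equal(annotate_promoter(gr(9400, 9600), genes), "promoter")
  # for the - strand gene, the promoter window lies above the gene end
  expect_equal(annotate_promoter(gr(35200, 35400), genes), "promoter")
  # exonic beats non-coding, promoter beats exonic
  expect_equal(annotate_promoter(gr(12100, 12200), genes, exons), "exonic")
  expect_equal(annotate_promoter(gr(50000, 50100), genes, exons), "non-coding")
  expect_error(annotate_promoter(gr(0, 10),
                                 GenomicRanges::GRanges("chrS",
                                                        IRanges::IRanges(1, 10),
                                                        strand = "*")),
               "strand")
  # random pCREs against toy genes match direct interval logic
  set.seed(52)
  pc <- random_granges(30, 5e4)
  lab <- annotate_promoter(pc, genes, exons)
  prom_plus <- c(10001 - 1000, 10001 + 100 - 1)   # 1-based closed
  prom_minus <- c(35000 - 100 + 1, 35000 + 1000)
  for (i in seq_along(pc)) {
    s <- GenomicRanges::start(pc)[i]
    e <- GenomicRanges::end(pc)[i]
    in_prom <- (s <= prom_plus[2] && e >= prom_plus[1]) ||
      (s <= prom_minus[2] && e >= prom_minus[1])
    in_exon <- s <= 12500 && e >= 12001
    want <- if (in_prom) "promoter" else if (in_exon) "exonic" else "non-coding"
    expect_identical(lab[i], want)
  }
})
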