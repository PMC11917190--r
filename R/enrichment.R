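#' Count query regions overlapping a reference set
#'
#' Number of query regions overlapping at least one reference peak by at
#' least one bp; each query region is counted once however many peaks it
#' touches.
#'
#' @param query,reference `GRanges` region sets.
#' @return Integer count.
#' @export
overlap_count <- function(query, reference) {
  sum(GenomicRanges::countOverlaps(query, reference, minoverlap = 1L) > 0)
}

# Merge 0-based half-open intervals into disjoint sorted intervals.
.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- numeric(0)
  me <- numeric(0)
  for (i in seq_along(start)) {
    if (length(ms) && start[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end[i])
    } else {
      ms <- c(ms, start[i])
      me <- c(me, end[i])
    }
  }
  list(start = ms, end = me)
}

# Vectorized test: does [qs, qe) overlap any merged reference interval?
.overlaps_any <- function(qs, qe, ref) {
  idx <- findInterval(qs, ref$start)
  hit <- idx >= 1L & qs < ref$end[pmax(idx, 1L)]
  nxt <- idx + 1L
  ok <- nxt <= length(ref$start)
  hit[ok] <- hit[ok] | ref$start[nxt[ok]] < qe[ok]
  hit
}

#' Randomly re-place regions within a universe
#'
#' Each query region is re-placed uniformly at random within the universe,
#' preserving its length; placed regions may overlap one another.
#'
#' @param query `GRanges` (or data.frame with 0-based `start`/`end`).
#' @param universe Numeric `c(start, end)` (0-based half-open) or a
#'   single-range `GRanges`.
#' @param seed Optional integer seed.
#' @param chrom Chromosome name for the output.
#' @return A `GRanges` of randomized regions with the original widths.
#' @export
permute_regions <- function(query, universe, seed = NULL, chrom = "chrS") {
  q <- .as_regions(query)
  u <- .as_universe(universe)
  w <- q$end - q$start
  if (any(w > u[2] - u[1])) {
    stop("a query region is longer than the universe")
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- u[1] + floor(stats::runif(nrow(q)) * (u[2] - u[1] - w + 1))
  GenomicRanges::GRanges(rep(chrom, nrow(q)),
                         IRanges::IRanges(start = starts + 1L, width = w))
}

.as_universe <- function(universe) {
  if (is(universe, "GRanges")) {
    stopifnot(length(universe) == 1L)
    universe <- c(start(universe) - 1L, end(universe))
  }
  if (length(universe) != 2L || universe[2] <= universe[1]) {
    stop("universe must be a nonempty interval c(start, end)")
  }
  as.numeric(universe)
}

#' Permutation test of region-set overlap
#'
#' Compares the observed number of query regions overlapping the reference
#' peaks with a null distribution obtained by re-placing the query regions
#' uniformly at random in the universe (`n` permutations, lengths
#' preserved).  The empirical p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n)` for enrichment (`<=` for
#' depletion).
#'
#' @param query,reference Nonempty `GRanges` sets.
#' @param universe Randomization universe, `c(start, end)` in bp (0-based
#'   half-open) or a single-range `GRanges`; typically the cis analysis
#'   window.
#' @param n Number of permutations (default 10000).
#' @param seed Optional integer seed (stored in the result).
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @return An `enrichment_result` one-row data.frame: `observed`,
#'   `null_mean`, `null_sd`, `z` (`NA` when `null_sd` is 0), `p`,
#'   `p_depletion`, `prop_overlap` (fraction of query regions hit),
#'   `n_query`, `n_perm`, `seed`, `fdr` (`NA`, filled by [bh_fdr()] across
#'   a family).
#' @export
permutation_enrichment <- function(query, reference, universe, n = 10000,
                                   seed = NULL,
                                   alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  if (length(query) == 0L) stop("query set is empty")
  if (length(reference) == 0L) stop("reference set is empty")
  q <- .as_regions(query)
  r <- .as_regions(reference)
  u <- .as_universe(universe)
  ref <- .merge_intervals(r$start, r$end)
  w <- q$end - q$start
  if (any(w > u[2] - u[1])) stop("a query region is longer than the universe")
  obs <- sum(.overlaps_any(q$start, q$end, ref))

  if (!is.null(seed)) set.seed(seed)
  m <- nrow(q)
  starts <- u[1] + floor(stats::runif(n * m) * rep(u[2] - u[1] - w + 1, each = n))
  ends <- starts + rep(w, each = n)
  hits <- .overlaps_any(starts, ends, ref)
  null <- rowSums(matrix(hits, nrow = n))

  mu <- mean(null)
  sdv <- stats::sd(null)
  z <- if (sdv > 0) (obs - mu) / sdv else NA_real_
  p_enr <- (1 + sum(null >= obs)) / (1 + n)
  p_dep <- (1 + sum(null <= obs)) / (1 + n)
  structure(data.frame(
    observed = obs, null_mean = mu, null_sd = sdv, z = z,
    p = if (alternative == "enrichment") p_enr else p_dep,
    p_depletion = p_dep,
    prop_overlap = obs / m,
    n_query = m, n_perm = n,
    seed = if (is.null(seed)) NA_integer_ else seed,
    fdr = NA_real_,
    alternative = alternative,
    stringsAsFactors = FALSE
  ), class = c("enrichment_result", "data.frame"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a validated front-end to
#' [stats::p.adjust()]): monotone non-decreasing in p-rank and capped at 1.
#'
#' @param pvalues Numeric p-values in (0, 1].
#' @return Adjusted values, same length and order as the input; empty input
#'   gives an empty result.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Average enrichment results over replicates
#'
#' For one pCRE-class x mark x cell combination tested against several
#' ChIP replicates, reports the arithmetic mean z-score and mean FDR.
#'
#' @param results A data.frame of `enrichment_result` rows (needs columns
#'   `z` and `fdr`).
#' @return A list with `mean_z`, `mean_fdr` and `n_replicates`.
#' @export
aggregate_replicates <- function(results) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("no replicate results to aggregate")
  list(mean_z = mean(results$z), mean_fdr = mean(results$fdr),
       n_replicates = nrow(results))
}

#' Run a family of enrichment tests with BH correction
#'
#' Tests every query set against every reference set, adjusts p-values
#' across the whole family (all tests of one invocation), and aggregates
#' replicate references of the same mark and cell line.
#'
#' @param queries Named list of `GRanges` (e.g. gained / lost pCREs).
#' @param references List of `GRanges` peak sets.
#' @param ref_info Data.frame describing `references`, with columns `mark`,
#'   `cell`, `replicate` (one row per reference set); defaults to set
#'   names.
#' @param universe Randomization universe (see
#'   [permutation_enrichment()]).
#' @param n Permutations per test (default 10000).
#' @param seed Optional integer base seed; test i uses `seed + i`.
#' @return A list with `tests` (per-test table incl. `fdr`) and `summary`
#'   (mean z and mean FDR per query x mark x cell).
#' @export
enrichment_table <- function(queries, references, ref_info = NULL,
                             universe, n = 10000, seed = NULL) {
  stopifnot(is.list(queries), is.list(references))
  if (is.null(ref_info)) {
    nm <- names(references)
    if (is.null(nm)) nm <- paste0("ref", seq_along(references))
    ref_info <- data.frame(mark = nm, cell = "NA", replicate = "rep1",
                           stringsAsFactors = FALSE)
  }
  stopifnot(nrow(ref_info) == length(references))
  rows <- list()
  k <- 0L
  for (iq in seq_along(queries)) {
    for (ir in seq_along(references)) {
      k <- k + 1L
      res <- permutation_enrichment(
        queries[[iq]], references[[ir]], universe, n = n,
        seed = if (is.null(seed)) NULL else seed + k
      )
      res$query <- names(queries)[iq]
      res$mark <- ref_info$mark[ir]
      res$cell <- ref_info$cell[ir]
      res$replicate <- ref_info$replicate[ir]
      rows[[k]] <- res
    }
  }
  tests <- do.call(rbind, rows)
  tests$fdr <- bh_fdr(tests$p)
  grp <- interaction(tests$query, tests$mark, tests$cell, drop = TRUE)
  summ <- do.call(rbind, lapply(split(tests, grp), function(g) {
    a <- aggregate_replicates(g)
    data.frame(query = g$query[1L], mark = g$mark[1L], cell = g$cell[1L],
               mean_z = a$mean_z, mean_fdr = a$mean_fdr,
               mean_prop_overlap = mean(g$prop_overlap),
               n_replicates = a$n_replicates, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(tests = tests, summary = summ)
}
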