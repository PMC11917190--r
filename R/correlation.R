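#' Rebin scored region sets into fixed-width bins
#'
#' Tiles a chromosome into `ceiling(chrom_length / width)` bins (the final
#' partial bin is kept).  Within each sample, region scores are converted
#' to standardized percentiles (average-tie rank divided by the number of
#' regions, so values lie in (0, 1]); every bin overlapped by a region
#' receives that percentile, the maximum winning where regions of one
#' sample collide.
#'
#' @param samples Named list of region sets (`GRanges` with a `score`
#'   column, or data.frames with 0-based `start`/`end`/`score`).
#' @param chrom_length Chromosome length in bp.
#' @param width Bin width in bp (default 100).
#' @return A `bin_matrix`: sparse `n_bins x n_samples` matrix of
#'   percentiles plus bookkeeping (`n_bins`, `width`, `chrom_length`).
#' @export
rebin <- function(samples, chrom_length, width = 100) {
  if (width <= 0) stop("width must be positive")
  if (!is.list(samples) || length(samples) == 0L) {
    stop("samples must be a nonempty named list")
  }
  if (is.null(names(samples))) names(samples) <- paste0("S", seq_along(samples))
  n_bins <- as.integer(ceiling(chrom_length / width))
  ii <- integer(0)
  jj <- integer(0)
  xx <- numeric(0)
  for (j in seq_along(samples)) {
    r <- .as_regions(samples[[j]])
    if (nrow(r) == 0L) next
    if (any(!is.finite(r$score)) || any(r$score < 0)) {
      stop("sample '", names(samples)[j], "' needs non-negative scores")
    }
    if (any(r$start < 0) || any(r$end > chrom_length)) {
      stop("sample '", names(samples)[j], "' has regions outside [0, chrom_length)")
    }
    pct <- rank(r$score, ties.method = "average") / nrow(r)
    b1 <- pmax(1L, as.integer(r$start %/% width) + 1L)
    b2 <- pmin(n_bins, as.integer((r$end - 1L) %/% width) + 1L)
    bins <- unlist(mapply(seq, b1, b2, SIMPLIFY = FALSE))
    vals <- rep(pct, b2 - b1 + 1L)
    agg <- tapply(vals, bins, max)
    ii <- c(ii, as.integer(names(agg)))
    jj <- c(jj, rep(j, length(agg)))
    xx <- c(xx, as.numeric(agg))
  }
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(n_bins, length(samples)),
                              dimnames = list(NULL, names(samples)))
  structure(list(mat = mat, n_bins = n_bins, width = width,
                 chrom_length = chrom_length, bin_index = seq_len(n_bins),
                 dropped = FALSE),
            class = "bin_matrix")
}

#' Drop bins no sample overlaps
#'
#' Removes bins whose row sum is zero across all samples and records the
#' sparsity of the retained matrix.
#'
#' @param matrix A `bin_matrix` from [rebin()].
#' @return The filtered `bin_matrix` with `bin_index` (retained bin
#'   numbers) and `sparsity` (fraction of zero entries) set.
#' @export
drop_empty <- function(matrix) {
  stopifnot(inherits(matrix, "bin_matrix"))
  keep <- Matrix::rowSums(matrix$mat) > 0
  if (!any(keep)) stop("all bins are empty; nothing to correlate")
  matrix$mat <- matrix$mat[keep, , drop = FALSE]
  matrix$bin_index <- matrix$bin_index[keep]
  matrix$sparsity <- 1 - Matrix::nnzero(matrix$mat) / length(matrix$mat)
  matrix$dropped <- TRUE
  matrix
}

#' Pairwise Pearson correlation of rebinned samples
#'
#' Symmetric correlation matrix over retained bins, with an average-linkage
#' hierarchical clustering order (on 1 - r) for heatmap display.  Samples
#' with zero variance get `NA` correlations.
#'
#' @param matrix A `bin_matrix`, ideally after [drop_empty()].
#' @return A list with `r` (correlation matrix, unit diagonal), `order`
#'   (display order of samples) and `hclust` (the clustering object, or
#'   `NULL` when fewer than 3 complete samples).
#' @export
pearson_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "bin_matrix"))
  m <- as.matrix(matrix$mat)
  if (ncol(m) < 2L) stop("need at least two samples")
  if (nrow(m) < 2L) stop("need at least two retained bins")
  r <- suppressWarnings(stats::cor(m))
  dg <- diag(r)
  dg[!is.na(dg)] <- 1
  diag(r) <- dg
  ok <- which(colSums(is.na(r)) < nrow(r) - 1L)
  hc <- NULL
  ord <- seq_len(ncol(r))
  if (length(ok) >= 3L) {
    sub <- r[ok, ok]
    sub[is.na(sub)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - sub), method = "average")
    ord <- c(ok[hc$order], setdiff(ord, ok))
  }
  list(r = r, order = ord, hclust = hc)
}
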