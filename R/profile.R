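#' Read a bedGraph file with per-line validation
#'
#' Minimal reader for 4-column bedGraph (chrom, start, end, value).
#' Malformed records raise an error naming the offending line, which is why
#' this reader is implemented in-package.
#'
#' @param path File path.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `count`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) stop("empty bedGraph file: ", path)
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 4L)) {
    stop("malformed bedGraph record at line ", which(nf < 4L)[1L],
         " of ", path, " (need 4 fields)")
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  count <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(count) |
                 end <= start | count < 0)
  if (length(bad)) {
    stop("malformed bedGraph record at line ", bad[1L], " of ", path)
  }
  data.frame(chrom = m[, 1L], start = start, end = end, count = count,
             stringsAsFactors = FALSE)
}

#' Write a bedGraph file
#'
#' @param x `data.frame` with columns chrom, start, end and a value column
#'   (named `count` or given by `value_col`).
#' @param path Output path.
#' @param value_col Name of the value column (default `"count"`).
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(x, path, value_col = "count") {
  out <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                    format(x$end, scientific = FALSE, trim = TRUE),
                    x[[value_col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load raw counts onto a fragment map
#'
#' Assigns each input record to the fragment containing its midpoint.
#' Counts landing in valid fragments accumulate on that fragment's NlaIII
#' end (a fragment's signal is the sum of its end counts); records in
#' invalid (blind, short or viewpoint-proximal) fragments, outside the map,
#' or on other chromosomes are dropped and tallied.
#'
#' @param x bedGraph path, a bedGraph-like `data.frame`
#'   (chrom/start/end/count), or a BED path/`data.frame` of aligned read
#'   positions (each record counts 1; set `format = "bed"`).
#' @param fmap A filtered `fragment_map` (viewpoint must be set).
#' @param replicate Replicate identifier stored on the profile.
#' @param format `"auto"`, `"bedGraph"` or `"bed"`.
#' @return A `vp_profile`: per valid fragment end, genomic coordinates,
#'   signed distance from the viewpoint, and `raw` counts
#'   (`normalized`/`smoothed` are filled by [normalize_profile()] and
#'   [smooth_profile()]).
#' @export
load_counts <- function(x, fmap, replicate = "rep1",
                        format = c("auto", "bedGraph", "bed")) {
  stopifnot(inherits(fmap, "fragment_map"))
  format <- match.arg(format)
  vp <- attr(fmap, "viewpoint")
  if (!is.finite(vp)) stop("fragment map has no viewpoint; run filter_fragments() first")

  if (is.character(x)) {
    x <- if (format == "bed") {
      b <- utils::read.table(x, sep = "\t", stringsAsFactors = FALSE)
      if (ncol(b) < 3L) stop("BED input needs at least 3 columns")
      data.frame(chrom = b[[1L]], start = b[[2L]], end = b[[3L]], count = 1)
    } else {
      read_bedgraph(x)
    }
  } else if (is.data.frame(x)) {
    if (!"count" %in% names(x)) x$count <- 1
  } else {
    stop("x must be a file path or a data.frame")
  }
  if (nrow(x) == 0L) stop("no input records")

  on_chrom <- x$chrom == attr(fmap, "chrom")
  mid <- floor((x$start + x$end) / 2)
  idx <- findInterval(mid, fmap$start)
  ok <- on_chrom & idx >= 1L & mid < fmap$end[pmax(idx, 1L)]
  assignable <- ok & fmap$valid[pmax(idx, 1L)]
  n_dropped <- sum(!assignable)
  if (!any(assignable)) stop("no records assignable to valid fragments")
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped (invalid fragment or off-map)")
  }

  vrows <- which(fmap$valid)
  raw <- numeric(length(vrows))
  tab <- tapply(x$count[assignable], idx[assignable], sum)
  raw[match(as.integer(names(tab)), vrows)] <- as.numeric(tab)

  pos <- (fmap$end_start[vrows] + fmap$end_end[vrows]) / 2
  structure(list(
    fmap_chrom = attr(fmap, "chrom"),
    viewpoint = vp,
    replicate = replicate,
    frag_rows = vrows,
    start = fmap$start[vrows],
    end = fmap$end[vrows],
    end_start = fmap$end_start[vrows],
    end_end = fmap$end_end[vrows],
    pos = pos,
    distance = pos - vp,
    raw = raw,
    normalized = NULL,
    smoothed = NULL,
    n_dropped = n_dropped
  ), class = "vp_profile")
}

#' Scale a profile to a fixed library size
#'
#' `normalized_i = raw_i * target_total / sum(raw)`, so the normalized
#' counts sum to `target_total` over valid fragment ends ("per million
#' ends" by default).
#'
#' @param profile A `vp_profile`.
#' @param target_total Target library size (default 1e6).
#' @return The profile with `normalized` filled.
#' @export
normalize_profile <- function(profile, target_total = 1e6) {
  stopifnot(inherits(profile, "vp_profile"))
  tot <- sum(profile$raw)
  if (tot <= 0) stop("cannot normalize an all-zero profile")
  profile$normalized <- profile$raw * target_total / tot
  profile$target_total <- target_total
  profile
}

# Centered running mean over fragment index.  A window of width w reaches
# floor(w/2) fragments left and w-1-floor(w/2) right of self (15+self+14 for
# w = 30).  Near the array edges the window is shrunk symmetrically: both
# reaches are truncated to min(i-1, n-i).
.running_mean <- function(x, window) {
  n <- length(x)
  l0 <- window %/% 2L
  r0 <- window - 1L - l0
  i <- seq_len(n)
  m <- pmin(i - 1L, n - i)
  l <- pmin(l0, m)
  r <- pmin(r0, m)
  cs <- cumsum(c(0, x))
  (cs[i + r + 1L] - cs[i - l]) / (l + r + 1)
}

#' Smooth a profile with a mean running window
#'
#' Applies a centered 30-fragment (by default) running mean over the
#' normalized counts, in fragment-index space.  The even window is centered
#' as 15 fragments left + self + 14 right; near the array edges it shrinks
#' symmetrically so the output has no missing values.
#'
#' @param profile A normalized `vp_profile`.
#' @param window Window width in fragments (default 30).
#' @return The profile with `smoothed` filled.
#' @export
smooth_profile <- function(profile, window = 30) {
  stopifnot(inherits(profile, "vp_profile"))
  if (is.null(profile$normalized)) {
    stop("profile must be normalized before smoothing")
  }
  n <- length(profile$normalized)
  if (n < window) {
    stop("profile has ", n, " fragment ends; need at least ", window)
  }
  profile$smoothed <- .running_mean(profile$normalized, window)
  profile$window <- window
  profile
}

#' Load, normalize and smooth in one step
#'
#' @inheritParams load_counts
#' @inheritParams normalize_profile
#' @inheritParams smooth_profile
#' @return A `vp_profile` with `raw`, `normalized` and `smoothed` filled.
#' @export
prepare_profile <- function(x, fmap, replicate = "rep1",
                            target_total = 1e6, window = 30) {
  p <- load_counts(x, fmap, replicate = replicate)
  p <- normalize_profile(p, target_total = target_total)
  smooth_profile(p, window = window)
}

#' Sum profile counts into fixed-width bins around the viewpoint
#'
#' Each valid fragment end whose midpoint lies within `viewpoint +/- span`
#' contributes its count to the bin containing the midpoint; 5 kb bins over
#' a +/-1 Mb window give 400 bins.
#'
#' @param profile A `vp_profile`.
#' @param bin Bin width in bp (default 5000).
#' @param span Half-window in bp (default 1e6); must be a multiple of `bin`.
#' @param use `"normalized"` (default; falls back to raw with a warning) or
#'   `"raw"`.
#' @return A `binned_counts` data.frame with columns `start`, `end`, `mid`,
#'   `count`, plus attributes `viewpoint`, `bin`, `span`.
#' @export
bin_counts <- function(profile, bin = 5000, span = 1e6,
                       use = c("normalized", "raw")) {
  stopifnot(inherits(profile, "vp_profile"))
  use <- match.arg(use)
  if (span %% bin != 0) stop("span must be a multiple of bin")
  vals <- if (use == "normalized") {
    if (is.null(profile$normalized)) {
      warning("profile not normalized; binning raw counts")
      profile$raw
    } else profile$normalized
  } else profile$raw
  vp <- profile$viewpoint
  nb <- as.integer(2 * span / bin)
  lo <- vp - span
  inwin <- profile$pos >= lo & profile$pos < vp + span
  bi <- floor((profile$pos[inwin] - lo) / bin) + 1L
  count <- numeric(nb)
  if (any(inwin)) {
    tab <- tapply(vals[inwin], bi, sum)
    count[as.integer(names(tab))] <- as.numeric(tab)
  }
  starts <- lo + bin * (seq_len(nb) - 1L)
  structure(data.frame(start = starts, end = starts + bin,
                       mid = starts + bin / 2, count = count),
            viewpoint = vp, bin = bin, span = span,
            chrom = profile$fmap_chrom, replicate = profile$replicate,
            class = c("binned_counts", "data.frame"))
}

#' Pearson correlation between two binned replicate profiles
#'
#' @param binned_a,binned_b `binned_counts` objects on identical bins.
#' @return A list with `r` (Pearson correlation, `NA` when either vector
#'   has zero variance) and `n` (number of bins used).
#' @export
replicate_correlation <- function(binned_a, binned_b) {
  stopifnot(inherits(binned_a, "binned_counts"),
            inherits(binned_b, "binned_counts"))
  if (nrow(binned_a) != nrow(binned_b) ||
      attr(binned_a, "bin") != attr(binned_b, "bin") ||
      attr(binned_a, "viewpoint") != attr(binned_b, "viewpoint")) {
    stop("binned profiles must share the same binning")
  }
  a <- binned_a$count
  b <- binned_b$count
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a binned profile; correlation undefined")
    return(list(r = NA_real_, n = length(a)))
  }
  list(r = stats::cor(a, b), n = length(a))
}

#' @export
print.vp_profile <- function(x, ...) {
  cat("4C viewpoint profile (", x$replicate, "): ",
      length(x$raw), " valid fragment ends on ", x$fmap_chrom,
      "; viewpoint ", x$viewpoint, "\n", sep = "")
  cat("  total raw counts:", sum(x$raw),
      if (!is.null(x$normalized)) "| normalized" else "",
      if (!is.null(x$smoothed)) "| smoothed" else "", "\n")
  invisible(x)
}
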