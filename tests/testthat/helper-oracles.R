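# Brute-force oracles, kept deliberately independent of the package's
# implementation paths.

# all occurrences of a motif by sliding-window comparison
oracle_find_sites <- function(seq, motif) {
  n <- nchar(seq)
  k <- nchar(motif)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    if (substring(seq, i, i + k - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# exhaustive isotonic (non-increasing) least squares: enumerate all
# consecutive-block partitions, set each block to its mean, keep feasible
# solutions, return the minimizer (valid for n <= 12)
oracle_isotonic_nonincreasing <- function(y) {
  n <- length(y)
  if (n == 1L) return(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
    bounds <- c(0L, cuts, n)
    fit <- numeric(n)
    means <- numeric(length(bounds) - 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[b] + 1L):bounds[b + 1L]
      means[b] <- mean(y[idx])
      fit[idx] <- means[b]
    }
    if (length(means) > 1L && any(diff(means) > 1e-12)) next
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-15) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# transitive-closure merging of 0-based half-open intervals with gap <= gap
oracle_merge <- function(start, end, gap) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  groups <- list()
  cs <- start[1L]
  ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] - ce <= gap) {
      ce <- max(ce, end[i])
    } else {
      groups[[length(groups) + 1L]] <- c(cs, ce)
      cs <- start[i]
      ce <- end[i]
    }
  }
  groups[[length(groups) + 1L]] <- c(cs, ce)
  do.call(rbind, groups)
}

# pairwise-loop overlap counting on 0-based half-open intervals
oracle_overlap_count <- function(qs, qe, rs, re) {
  hit <- 0L
  for (i in seq_along(qs)) {
    for (j in seq_along(rs)) {
      if (qs[i] < re[j] && qe[i] > rs[j]) {
        hit <- hit + 1L
        break
      }
    }
  }
  hit
}

# brute-force shared/gained/lost classification on 0-based intervals
oracle_classify <- function(exp_df, base_dfs, min_overlap = 1) {
  overlaps <- function(s1, e1, s2, e2) {
    min(e1, e2) - max(s1, s2) >= min_overlap
  }
  base <- do.call(rbind, base_dfs)
  merged <- if (nrow(base)) {
    m <- oracle_merge(base$start, base$end, gap = -1)
    data.frame(start = m[, 1], end = m[, 2])
  } else data.frame(start = numeric(0), end = numeric(0))
  shared <- gained <- 0L
  for (i in seq_len(nrow(exp_df))) {
    any_hit <- FALSE
    for (j in seq_len(nrow(merged))) {
      if (overlaps(exp_df$start[i], exp_df$end[i], merged$start[j], merged$end[j])) {
        any_hit <- TRUE
        break
      }
    }
    if (any_hit) shared <- shared + 1L else gained <- gained + 1L
  }
  lost <- 0L
  for (j in seq_len(nrow(merged))) {
    any_hit <- FALSE
    for (i in seq_len(nrow(exp_df))) {
      if (overlaps(exp_df$start[i], exp_df$end[i], merged$start[j], merged$end[j])) {
        any_hit <- TRUE
        break
      }
    }
    if (!any_hit) lost <- lost + 1L
  }
  c(shared = shared, gained = gained, lost = lost)
}

# exact binomial upper tail by direct summation of dbinom
oracle_binom_tail <- function(q, size, prob) {
  if (q > size) return(0)
  sum(stats::dbinom(q:size, size, prob))
}

# random GRanges helper (0-based starts drawn on [0, span))
random_granges <- function(n, span, max_width = 500, chrom = "chrS") {
  w <- sample.int(max_width, n, replace = TRUE)
  s <- floor(runif(n) * (span - w))
  GenomicRanges::GRanges(rep(chrom, n),
                         IRanges::IRanges(start = s + 1, width = w))
}
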