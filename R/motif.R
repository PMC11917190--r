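.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Count canonical k-mers on both strands
#'
#' Counts every overlapping k-mer occurrence on the forward and reverse
#' strand (windows containing `N` are skipped) and collapses each k-mer
#' with its reverse complement into a canonical form (the lexicographic
#' minimum of the pair).  A palindromic duplex occurrence therefore counts
#' 2, like any other duplex position seen from both strands.
#'
#' @param sequences Character vector or `DNAStringSet` (A/C/G/T/N).
#' @param k Oligomer length (6 and 7 are the usual choices; any k >= 1
#'   works).
#' @return Named numeric vector of counts over all canonical k-mer classes
#'   (class `oligo_counts`), with attributes `k`, `n_positions` (number of
#'   N-free scanned windows on both strands) and `base_freq` (both-strand
#'   mononucleotide frequencies of the input).
#' @export
count_oligos <- function(sequences, k) {
  if (is.character(sequences)) sequences <- DNAStringSet(toupper(sequences))
  stopifnot(is(sequences, "DNAStringSet"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (length(sequences) == 0L || sum(width(sequences)) == 0L) {
    sequences <- DNAStringSet()
  }
  if (length(sequences) && all(width(sequences) < k)) {
    warning("all sequences are shorter than k; zero counts")
  }
  fwd <- if (length(sequences)) {
    colSums(oligonucleotideFrequency(sequences, k))
  } else {
    stats::setNames(rep(0, 4^k), sort(.all_kmers(k)))
  }
  rev <- if (length(sequences)) {
    colSums(oligonucleotideFrequency(reverseComplement(sequences), k))
  } else fwd
  tot <- fwd + rev
  canon <- .canonical(names(tot))
  counts <- tapply(tot, canon, sum)
  counts <- counts[order(names(counts))]
  bf <- if (length(sequences)) {
    f <- colSums(Biostrings::letterFrequency(sequences, c("A", "C", "G", "T")))
    f2 <- f + f[c("T", "G", "C", "A")] # both strands
    names(f2) <- c("A", "C", "G", "T")
    f2 / sum(f2)
  } else c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  structure(as.numeric(counts),
            names = names(counts),
            k = k,
            n_positions = 2 * sum(fwd),
            base_freq = bf,
            class = "oligo_counts")
}

.all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

.canonical <- function(kmers) {
  rc <- .revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Binomial over-representation of canonical k-mers
#'
#' For each canonical k-mer class, the expected occurrence count under an
#' order-0 background is `n_positions * q` with
#' `q = Pr(word) + Pr(revcomp(word))` (one term for palindromes).  Because
#' every duplex occurrence is seen from both strands, counts come in pairs;
#' the binomial tail is therefore evaluated on duplex occurrences
#' (`observed / 2` successes in `n_positions / 2` trials), which keeps the
#' test calibrated while observed and expected stay on the both-strand
#' scale.  The E-value multiplies the p-value by the number of canonical
#' classes tested.
#'
#' @param counts An `oligo_counts` vector from [count_oligos()] (or a named
#'   count vector with `n_positions` supplied).
#' @param background Named base frequencies (A/C/G/T summing to 1); default
#'   is the order-0 model estimated from the counted input, falling back to
#'   uniform.
#' @param n_positions Number of scanned windows on both strands; default
#'   taken from `counts`.
#' @return An `oligo_enrichment` data.frame sorted by E-value: `oligo`,
#'   `k`, `observed`, `expected`, `p`, `evalue`.
#' @export
oligo_enrichment <- function(counts, background = NULL, n_positions = NULL) {
  if (is.null(n_positions)) n_positions <- attr(counts, "n_positions")
  if (is.null(n_positions) || n_positions <= 0) {
    stop("n_positions must be supplied (and positive)")
  }
  if (is.null(background)) {
    background <- attr(counts, "base_freq")
    if (is.null(background)) background <- c(A = .25, C = .25, G = .25, T = .25)
  }
  if (abs(sum(background) - 1) > 1e-6) stop("background frequencies must sum to 1")
  oligos <- names(counts)
  k <- unique(nchar(oligos))
  stopifnot(length(k) == 1L)

  pr_word <- function(w) {
    prod(background[strsplit(w, "")[[1L]]])
  }
  rc <- .revcomp(oligos)
  q <- vapply(oligos, pr_word, numeric(1)) +
    ifelse(rc != oligos, vapply(rc, pr_word, numeric(1)), 0)
  obs <- as.numeric(counts)
  if (any(q == 0 & obs > 0)) {
    stop("degenerate background: a zero-probability oligo was observed")
  }
  n_dup <- n_positions / 2
  obs_dup <- ceiling(obs / 2)
  p <- stats::pbinom(obs_dup - 1, n_dup, q, lower.tail = FALSE)
  p[q == 0] <- 1
  ev <- p * length(oligos)
  out <- data.frame(oligo = oligos, k = k, observed = obs,
                    expected = n_positions * q, p = p, evalue = ev,
                    stringsAsFactors = FALSE)
  out <- out[order(out$evalue, out$p, out$oligo), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_positions = n_positions, background = background,
            class = c("oligo_enrichment", "data.frame"))
}

# -- greedy assembly of significant oligos into count matrices ---------------

.unit_from_oligo <- function(oligo, weight) {
  letters <- strsplit(oligo, "")[[1L]]
  mat <- matrix(0, nrow = 4, ncol = length(letters),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(match(letters, rownames(mat)), seq_along(letters))] <- weight
  list(mat = mat, consensus = oligo, members = oligo)
}

.unit_rc <- function(u) {
  m <- u$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(u$mat))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  list(mat = m, consensus = .revcomp(u$consensus),
       members = u$members)
}

.consensus_of <- function(mat) {
  paste(rownames(mat)[apply(mat, 2, which.max)], collapse = "")
}

# longest suffix of a equal to prefix of b
.overlap_len <- function(a, b, min_overlap) {
  top <- min(nchar(a), nchar(b))
  if (top < min_overlap) return(0L)
  for (ov in seq(top, min_overlap)) {
    if (substring(a, nchar(a) - ov + 1L, nchar(a)) == substring(b, 1L, ov)) {
      return(ov)
    }
  }
  0L
}

.merge_units <- function(a, b, ov) {
  offset <- ncol(a$mat) - ov
  wid <- max(ncol(a$mat), offset + ncol(b$mat))
  m <- matrix(0, 4, wid, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[, seq_len(ncol(a$mat))] <- a$mat
  m[, offset + seq_len(ncol(b$mat))] <- m[, offset + seq_len(ncol(b$mat))] + b$mat
  list(mat = m, consensus = .consensus_of(m),
       members = c(a$members, b$members))
}

#' Assemble significant oligos into consensus count matrices
#'
#' Greedy agglomeration: repeatedly merges the pair of units (each
#' orientation of each unit considered) with the longest exact overlap of
#' at least `min_overlap`, adding observed-count-weighted base counts
#' column-wise; oligos that never merge become singleton matrices.
#'
#' @param oligos Character vector of oligos, or an `oligo_enrichment`
#'   data.frame (its `oligo` column is used and `observed` become the
#'   weights).
#' @param weights Optional observed counts used as column weights (default
#'   1 per oligo).
#' @param min_overlap Minimum exact overlap merged (default `min(k) - 2`).
#' @return A list of `consensus_matrix` objects, each with `mat` (4 x width
#'   count matrix), `consensus` and `members`.
#' @export
assemble_matrices <- function(oligos, weights = NULL, min_overlap = NULL) {
  if (inherits(oligos, "oligo_enrichment") || is.data.frame(oligos)) {
    weights <- oligos$observed
    oligos <- oligos$oligo
  }
  if (length(oligos) == 0L) return(list())
  if (is.null(weights)) weights <- rep(1, length(oligos))
  if (is.null(min_overlap)) min_overlap <- max(1L, min(nchar(oligos)) - 2L)

  units <- mapply(.unit_from_oligo, oligos, weights, SIMPLIFY = FALSE)
  repeat {
    best <- list(ov = 0L)
    nu <- length(units)
    if (nu < 2L) break
    for (i in seq_len(nu)) {
      for (j in seq_len(nu)) {
        if (i == j) next
        for (flip in c(FALSE, TRUE)) {
          bj <- if (flip) .unit_rc(units[[j]]) else units[[j]]
          ov <- .overlap_len(units[[i]]$consensus, bj$consensus, min_overlap)
          if (ov > best$ov) best <- list(ov = ov, i = i, j = j, flip = flip)
        }
      }
    }
    if (best$ov < min_overlap || best$ov == 0L) break
    bj <- if (best$flip) .unit_rc(units[[best$j]]) else units[[best$j]]
    merged <- .merge_units(units[[best$i]], bj, best$ov)
    units <- c(units[-c(best$i, best$j)], list(merged))
  }
  lapply(units, function(u) structure(u, class = "consensus_matrix"))
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("consensus matrix", x$consensus, "(width", ncol(x$mat), ") from",
      length(x$members), "oligo(s)\n")
  print(x$mat)
  invisible(x)
}

#' Write matrices in MEME minimal motif format
#'
#' @param matrices List of `consensus_matrix` objects.
#' @param path Output path.
#' @param background Named A/C/G/T frequencies for the header (default
#'   uniform).
#' @return The path, invisibly.
#' @export
write_meme <- function(matrices, path,
                       background = c(A = .25, C = .25, G = .25, T = .25)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background["A"],
                       background["C"], background["G"], background["T"]),
               ""), con)
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]$mat
    freq <- sweep(m, 2, pmax(colSums(m), 1e-12), "/")
    writeLines(sprintf("MOTIF %s m%d", matrices[[i]]$consensus, i), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(m), max(1, round(max(colSums(m))))), con)
    for (jj in seq_len(ncol(m))) {
      writeLines(paste(sprintf("%.6f", freq[, jj]), collapse = "  "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write matrices in a TRANSFAC-like count format
#'
#' @inheritParams write_meme
#' @return The path, invisibly.
#' @export
write_transfac <- function(matrices, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]$mat
    writeLines(c(sprintf("ID m%d", i), sprintf("BF %s", matrices[[i]]$consensus),
                 "P0\tA\tC\tG\tT"), con)
    for (jj in seq_len(ncol(m))) {
      writeLines(sprintf("%02d\t%g\t%g\t%g\t%g", jj, m["A", jj], m["C", jj],
                         m["G", jj], m["T", jj]), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
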