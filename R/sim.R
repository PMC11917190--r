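#' Simulation configuration
#'
#' Bundles every parameter of the synthetic 4C experiment.  Defaults
#' describe the study conditions the rest of the package is exercised
#' against: a 2 Mb cis window around a central viewpoint, restriction-site
#' densities giving roughly 2,000 valid NlaIII-DpnII fragments, a
#' power-law distance decay of expected contact counts, and
#' negative-binomial replicate noise.
#'
#' @param genome_length Genome length in bp (> 0; at least ~10 kb is
#'   recommended for a digestible map).
#' @param site_rate_primary,site_rate_secondary Expected NlaIII / DpnII
#'   recognition sites per kb.  Occurrences are planted or knocked out by
#'   substitution until the realized count is close to
#'   `rate * genome_length / 1000`.  `NA` leaves the natural rate of the
#'   random sequence (~3.9/kb each for uniform base composition).
#' @param viewpoint_pos Viewpoint position in bp (0-based).
#' @param decay_amplitude Expected count at distance 0.
#' @param decay_exponent Power-law exponent alpha > 0.
#' @param decay_scale Distance scale s in bp: expected count at distance d
#'   is `decay_amplitude * (1 + |d|/s)^(-decay_exponent)`.
#' @param planted_interactions List of planted interactions, each a list
#'   with elements `center` (bp), `half_width` (in valid fragments) and
#'   `fold` (fold-enhancement >= 1).
#' @param nb_dispersion Negative-binomial size parameter k > 0 (variance
#'   `mu + mu^2/k`); `Inf` gives Poisson noise.
#' @param n_replicates Number of replicates (>= 2; the interaction caller
#'   requires interactions to appear in every replicate).
#' @param seed Integer seed driving all randomness of the simulation.
#' @param chrom Chromosome name used in emitted files.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 2e6,
                       site_rate_primary = 1.2,
                       site_rate_secondary = 1.2,
                       viewpoint_pos = genome_length / 2,
                       decay_amplitude = 300,
                       decay_exponent = 1,
                       decay_scale = 2e4,
                       planted_interactions = list(),
                       nb_dispersion = 5,
                       n_replicates = 2,
                       seed = 1,
                       chrom = "chrS") {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    stop("genome_length must be > 0")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (decay_amplitude <= 0 || decay_exponent <= 0 || decay_scale <= 0) {
    stop("decay parameters must be positive")
  }
  if (viewpoint_pos < 0 || viewpoint_pos >= genome_length) {
    stop("viewpoint_pos must lie within [0, genome_length)")
  }
  for (p in planted_interactions) {
    if (!all(c("center", "half_width", "fold") %in% names(p))) {
      stop("each planted interaction needs center, half_width and fold")
    }
    if (p$fold < 1) stop("fold-enhancement must be >= 1")
  }
  structure(list(
    genome_length = as.integer(genome_length),
    site_rate_primary = site_rate_primary,
    site_rate_secondary = site_rate_secondary,
    viewpoint_pos = viewpoint_pos,
    decay_amplitude = decay_amplitude,
    decay_exponent = decay_exponent,
    decay_scale = decay_scale,
    planted_interactions = planted_interactions,
    nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    chrom = chrom
  ), class = "sim_config")
}

# Plant `n` copies of `motif` at positions that do not clash with existing
# CATG/GATC occurrences or with one another; returns the modified sequence.
.plant_motifs <- function(chars, motif, n, forbidden) {
  L <- length(chars)
  k <- nchar(motif)
  placed <- 0L
  tries <- 0L
  mot <- strsplit(motif, "")[[1L]]
  while (placed < n && tries < 50L * n + 100L) {
    tries <- tries + 1L
    p <- sample.int(L - k + 1L, 1L)
    if (any(forbidden[p:(p + k - 1L)])) next
    chars[p:(p + k - 1L)] <- mot
    forbidden[max(1L, p - k + 1L):min(L, p + 2L * k - 2L)] <- TRUE
    placed <- placed + 1L
  }
  list(chars = chars, forbidden = forbidden)
}

#' Simulate a random genome with controlled restriction-site density
#'
#' Draws a uniform random A/C/G/T sequence, then plants or knocks out CATG
#' and GATC occurrences (by base substitution; clashes are re-sampled) until
#' the realized counts are close to the configured per-kb rates.
#'
#' @param config A [sim_config()].
#' @param fasta Optional path; when given the genome is written as FASTA.
#' @return A [Biostrings::DNAStringSet] of length one, named after
#'   `config$chrom`.
#' @export
simulate_genome <- function(config, fasta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  set.seed(config$seed)
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  targets <- c(NlaIII = config$site_rate_primary,
               DpnII = config$site_rate_secondary) * L / 1000
  motifs <- c(NlaIII = "CATG", DpnII = "GATC")

  for (iter in 1:6) {
    seqstr <- paste(chars, collapse = "")
    occ <- lapply(motifs, function(m) find_sites(seqstr, names(which(motifs == m)))$pos)
    done <- TRUE
    # forbidden positions: bases inside any current occurrence of either motif
    forbidden <- logical(L)
    for (ps in occ) {
      for (d in 0:3) forbidden[ps + 1L + d] <- TRUE
    }
    for (enz in names(motifs)) {
      tgt <- targets[[enz]]
      if (!is.finite(tgt)) next
      cur <- length(occ[[enz]])
      diff <- round(tgt) - cur
      tol <- max(2, round(0.02 * max(tgt, 1)))
      if (abs(diff) <= tol) next
      done <- FALSE
      if (diff > 0) {
        res <- .plant_motifs(chars, motifs[[enz]], diff, forbidden)
        chars <- res$chars
        forbidden <- res$forbidden
      } else {
        kill <- occ[[enz]][sample.int(length(occ[[enz]]), -diff)]
        # mutate the second base of each doomed occurrence
        for (p in kill) {
          old <- chars[p + 2L]
          chars[p + 2L] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
    }
    if (done) break
  }

  out <- DNAStringSet(paste(chars, collapse = ""))
  names(out) <- config$chrom
  if (!is.null(fasta)) writeXStringSet(out, fasta)
  out
}

#' Simulate replicated 4C fragment-end counts with planted interactions
#'
#' Expected counts follow the distance decay
#' `mu(d) = decay_amplitude * (1 + |d|/decay_scale)^(-decay_exponent)`,
#' multiplied by the fold-enhancement inside each planted interaction, and
#' are drawn independently per replicate from a negative-binomial with the
#' configured dispersion.  One count is emitted per primary-enzyme (NlaIII)
#' fragment end of every fragment, valid or not; the profile loader later
#' keeps only valid fragments.
#'
#' @param fmap A filtered [digest()] fragment map (viewpoint set).
#' @param config A [sim_config()]; `viewpoint_pos` must lie inside the map.
#' @param outdir Optional directory: per-replicate bedGraph files
#'   (`counts_rep<i>.bedGraph`) and `sim_truth.json` are written there.
#' @return A list with `counts` (per-replicate `data.frame`s of
#'   chrom/start/end/count over fragment ends), `ends` (the fragment-end
#'   table), and `truth` (a `sim_truth` list recording planted regions and
#'   the seed).
#' @export
simulate_4c_counts <- function(fmap, config, outdir = NULL) {
  stopifnot(inherits(fmap, "fragment_map"), inherits(config, "sim_config"))
  if (nrow(fmap) == 0L) stop("fragment map is empty")
  L <- attr(fmap, "genome_length")
  vp <- config$viewpoint_pos
  if (vp < 0 || vp >= L) stop("viewpoint lies outside the genome span")

  ends <- .primary_ends(fmap)
  if (nrow(ends) == 0L) stop("fragment map has no primary-enzyme ends")
  pos <- (ends$start + ends$end) / 2
  d <- pos - vp
  mu <- config$decay_amplitude *
    (1 + abs(d) / config$decay_scale)^(-config$decay_exponent)

  # planted interactions: half_width counted in *valid* fragments around the
  # valid fragment containing (or nearest to) the centre
  fold <- rep(1, nrow(ends))
  planted <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), fold = numeric(0))
  vrows <- which(fmap$valid)
  for (p in config$planted_interactions) {
    if (length(vrows) == 0L) stop("no valid fragments to plant interactions in")
    inside <- fmap$start[vrows] <= p$center & fmap$end[vrows] > p$center
    i <- if (any(inside)) which(inside)[1L] else
      which.min(abs((fmap$start[vrows] + fmap$end[vrows]) / 2 - p$center))
    lo <- max(1L, i - p$half_width)
    hi <- min(length(vrows), i + p$half_width)
    rs <- fmap$start[vrows[lo]]
    re <- fmap$end[vrows[hi]]
    hit <- pos >= rs & pos < re
    fold[hit] <- pmax(fold[hit], p$fold)
    planted <- rbind(planted, data.frame(chrom = attr(fmap, "chrom"),
                                         start = rs, end = re, fold = p$fold))
  }

  set.seed(config$seed)
  counts <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    m <- mu * fold
    cnt <- if (is.finite(config$nb_dispersion)) {
      stats::rnbinom(length(m), size = config$nb_dispersion, mu = m)
    } else {
      stats::rpois(length(m), m)
    }
    counts[[r]] <- data.frame(chrom = ends$chrom, start = ends$start,
                              end = ends$end, count = cnt,
                              stringsAsFactors = FALSE)
  }
  names(counts) <- paste0("rep", seq_along(counts))

  truth <- structure(list(planted_regions = planted,
                          enrichment_design = NULL,
                          seed = config$seed),
                     class = "sim_truth")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_along(counts)) {
      write_bedgraph(counts[[r]],
                     file.path(outdir, sprintf("counts_rep%d.bedGraph", r)))
    }
    jsonlite::write_json(unclass(truth),
                         file.path(outdir, "sim_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(counts = counts, ends = ends, truth = truth)
}

#' Simulate a ChIP peak set with a planted overlap fraction
#'
#' Places `round(n_peaks * overlap_fraction)` peaks so that each overlaps a
#' distinct query region (recycling queries only if there are more such
#' peaks than queries) and scatters the remainder uniformly in the
#' universe.  Every peak carries a positive score.
#'
#' @param query Query region set (`GRanges` or data.frame with
#'   `start`/`end`, 0-based half-open).
#' @param universe Numeric `c(start, end)` interval (0-based half-open)
#'   containing the query.
#' @param n_peaks Number of peaks.
#' @param overlap_fraction Fraction of peaks planted onto queries, in [0,1].
#' @param width_dist `c(mean, sd)` of the normal peak-width distribution in
#'   bp (widths floored at 20 bp).
#' @param seed Optional integer seed.
#' @param chrom Chromosome name.
#' @return A list with `peaks` (a `GRanges` with a `score` column) and
#'   `truth` (a `sim_truth` recording the planted design).
#' @export
simulate_chip_peaks <- function(query, universe, n_peaks,
                                overlap_fraction, width_dist = c(500, 100),
                                seed = NULL, chrom = "chrS") {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]")
  }
  q <- .as_regions(query)
  if (overlap_fraction > 0 && nrow(q) == 0L) {
    stop("overlap_fraction > 0 requires a nonempty query set")
  }
  if (!is.null(seed)) set.seed(seed)
  u0 <- universe[1]
  u1 <- universe[2]
  if (u1 <= u0) stop("universe must be a nonempty interval")

  n_hit <- round(n_peaks * overlap_fraction)
  n_bg <- n_peaks - n_hit
  starts <- integer(0)
  widths <- integer(0)
  if (n_peaks > 0) {
    widths <- pmax(20L, as.integer(round(stats::rnorm(n_peaks, width_dist[1],
                                                      width_dist[2]))))
  }
  if (n_hit > 0) {
    idx <- rep(sample.int(nrow(q)), length.out = n_hit)
    for (j in seq_len(n_hit)) {
      w <- widths[j]
      qs <- q$start[idx[j]]
      qe <- q$end[idx[j]]
      lo <- max(u0, qs - w + 1L)
      hi <- min(qe - 1L, u1 - w)
      if (hi < lo) hi <- lo
      starts <- c(starts, lo + floor(stats::runif(1) * (hi - lo + 1)))
    }
  }
  if (n_bg > 0) {
    w <- widths[n_hit + seq_len(n_bg)]
    starts <- c(starts, u0 + floor(stats::runif(n_bg) * pmax(1, u1 - u0 - w + 1)))
  }
  score <- if (n_peaks > 0) round(stats::rexp(n_peaks, 1 / 50) + 1, 2) else numeric(0)
  peaks <- GenomicRanges::GRanges(
    seqnames = rep(chrom, n_peaks),
    ranges = IRanges::IRanges(start = starts + 1L, width = widths)
  )
  if (n_peaks > 0) peaks <- GenomicRanges::sort(peaks)
  S4Vectors::mcols(peaks)$score <- score
  truth <- structure(list(planted_regions = NULL,
                          enrichment_design = list(
                            n_peaks = n_peaks,
                            overlap_fraction = overlap_fraction),
                          seed = seed),
                     class = "sim_truth")
  list(peaks = peaks, truth = truth)
}

# Coerce GRanges / data.frame region sets to a 0-based half-open data.frame.
.as_regions <- function(x) {
  if (is(x, "GRanges")) {
    data.frame(start = start(x) - 1L, end = end(x),
               score = if (!is.null(x$score)) x$score else
                 rep(NA_real_, length(x)))
  } else if (is.data.frame(x)) {
    stopifnot(all(c("start", "end") %in% names(x)))
    data.frame(start = x$start, end = x$end,
               score = if ("score" %in% names(x)) x$score else
                 rep(NA_real_, nrow(x)))
  } else {
    stop("region set must be a GRanges or a data.frame with start/end")
  }
}
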