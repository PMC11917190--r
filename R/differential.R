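#' Classify pCREs as shared, gained or lost
#'
#' Anchored on the expressing cell line: an expressing-line pCRE that
#' overlaps (by at least `min_overlap` bp) a pCRE of at least one baseline
#' line is `shared`, otherwise `gained`.  Baseline pCREs (merged across
#' baseline lines so each region is counted once) overlapping no
#' expressing-line pCRE are `lost`.  Shared and gained regions are reported
#' in expressing-line coordinates.
#'
#' @param expressing `GRanges` of pCREs in the expressing cell line.
#' @param baselines List of `GRanges` pCRE sets for the baseline lines.
#' @param min_overlap Minimum overlap in bp defining "present in" (default
#'   1).
#' @return A `classified_pcres` list: `regions` (a `GRanges` with a
#'   `class` column covering all three classes), `counts` (named vector
#'   shared/gained/lost) and `total` (their sum, which equals the number of
#'   distinct merged regions across all cell lines).
#' @export
classify_pcres <- function(expressing, baselines, min_overlap = 1) {
  if (!is(expressing, "GRanges")) stop("expressing must be a GRanges")
  if (is(baselines, "GRanges")) baselines <- list(baselines)
  if (!length(baselines) || !all(vapply(baselines, is, logical(1), "GRanges"))) {
    stop("baselines must be a list of GRanges")
  }
  base_all <- suppressWarnings(Reduce(c, baselines))
  if (length(expressing) == 0L && length(base_all) == 0L) {
    stop("both the expressing and baseline pCRE sets are empty")
  }
  base_merged <- GenomicRanges::reduce(base_all)

  in_base <- GenomicRanges::countOverlaps(expressing, base_merged,
                                          minoverlap = min_overlap) > 0
  lost <- base_merged[GenomicRanges::countOverlaps(
    base_merged, expressing, minoverlap = min_overlap) == 0]

  cls <- c(ifelse(in_base, "shared", "gained"),
           rep("lost", length(lost)))
  regions <- suppressWarnings(c(GenomicRanges::granges(expressing), GenomicRanges::granges(lost)))
  S4Vectors::mcols(regions)$class <- cls
  counts <- c(shared = sum(in_base), gained = sum(!in_base),
              lost = length(lost))
  structure(list(regions = regions, counts = counts,
                 total = sum(counts)),
            class = "classified_pcres")
}

#' @export
print.classified_pcres <- function(x, ...) {
  cat("pCRE classes:", paste(names(x$counts), x$counts, collapse = ", "),
      sprintf("(total %d distinct regions)\n", x$total))
  invisible(x)
}

#' Distance class of pCREs relative to the viewpoint
#'
#' Near-cis: midpoint within 0.2 Mb of the viewpoint; medium-cis: between
#' 0.2 and 0.5 Mb inclusive; far-cis: beyond 0.5 Mb.  The boundary at
#' exactly 0.2 Mb (and 0.5 Mb) falls in the medium class.
#'
#' @param x A `GRanges` of pCREs, or a numeric vector of absolute
#'   distances in bp.
#' @param viewpoint Viewpoint position in bp (required for `GRanges`
#'   input).
#' @param viewpoint_chrom Viewpoint chromosome; pCREs on another
#'   chromosome (trans) raise an error, the pipeline being cis-only.
#' @param near,far Class boundaries in bp (defaults 2e5 and 5e5).
#' @return Factor with levels `near`, `medium`, `far`.
#' @export
distance_class <- function(x, viewpoint = NULL, viewpoint_chrom = NULL,
                           near = 2e5, far = 5e5) {
  if (is(x, "GRanges")) {
    if (is.null(viewpoint)) stop("viewpoint position required")
    if (!is.null(viewpoint_chrom) &&
        any(as.character(GenomicRanges::seqnames(x)) != viewpoint_chrom)) {
      stop("trans pCRE encountered; the analysis is cis-only")
    }
    mid <- floor((start(x) - 1 + end(x)) / 2)
    d <- abs(mid - viewpoint)
  } else {
    d <- abs(as.numeric(x))
  }
  factor(ifelse(d < near, "near", ifelse(d <= far, "medium", "far")),
         levels = c("near", "medium", "far"))
}

#' Smoothed density of pCRE distances per class
#'
#' Gaussian kernel density of absolute viewpoint distances, one density per
#' pCRE class, each integrating to one.  Classes with fewer than two pCREs
#' are omitted with a warning.
#'
#' @param classified A `classified_pcres` object (or a `GRanges` with a
#'   `class` metadata column).
#' @param viewpoint Viewpoint position in bp.
#' @param bw Kernel bandwidth, passed to [stats::density()] (default
#'   `"nrd0"`).
#' @return Named list of `density` objects, one per class present.
#' @export
distance_density <- function(classified, viewpoint, bw = "nrd0") {
  regions <- if (inherits(classified, "classified_pcres")) {
    classified$regions
  } else classified
  mid <- floor((start(regions) - 1 + end(regions)) / 2)
  d <- abs(mid - viewpoint)
  cls <- S4Vectors::mcols(regions)$class
  out <- list()
  for (cl in unique(cls)) {
    dd <- d[cls == cl]
    if (length(dd) < 2L) {
      warning("class '", cl, "' has fewer than 2 pCREs; density omitted")
      next
    }
    bw_use <- bw
    if (is.character(bw) && stats::sd(dd) == 0) {
      # all pCREs at one distance: automatic bandwidths degenerate
      bw_use <- max(1, 0.01 * (abs(dd[1L]) + 1))
    }
    out[[cl]] <- stats::density(dd, bw = bw_use)
  }
  out
}

#' Promoter / exonic / non-coding annotation of pCREs
#'
#' A pCRE overlapping the strand-adjusted window
#' `[TSS - upstream, TSS + downstream)` of any gene is `promoter`; failing
#' that, a pCRE overlapping an exon is `exonic`; all others are
#' `non-coding` (precedence promoter > exonic > non-coding).
#'
#' @param pcres `GRanges` of pCREs.
#' @param gene_models `GRanges` of gene bodies with strand set (`*` is an
#'   error; the TSS is strand-dependent).
#' @param exons Optional `GRanges` of exons.
#' @param upstream,downstream Promoter window in bp around the TSS
#'   (defaults 1000 and 100).
#' @return Character vector of labels, one per pCRE.
#' @export
annotate_promoter <- function(pcres, gene_models, exons = NULL,
                              upstream = 1000, downstream = 100) {
  if (!is(gene_models, "GRanges")) stop("gene_models must be a GRanges")
  if (any(as.character(strand(gene_models)) == "*")) {
    stop("gene_models must carry strand information")
  }
  prom <- GenomicRanges::promoters(gene_models, upstream = upstream,
                                   downstream = downstream)
  prom <- GenomicRanges::trim(prom)
  lab <- rep("non-coding", length(pcres))
  if (!is.null(exons) && length(exons)) {
    lab[GenomicRanges::countOverlaps(pcres, exons) > 0] <- "exonic"
  }
  lab[GenomicRanges::countOverlaps(pcres, prom) > 0] <- "promoter"
  lab
}
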