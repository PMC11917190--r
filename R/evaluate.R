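#' Resolution of the smoothed profile in bp
#'
#' Half the smoothing window expressed in genomic distance: the median
#' spacing between consecutive valid fragment-end midpoints times
#' `window / 2`.  Calls made on a `window`-fragment smoothed profile cannot
#' localize interactions more finely than this, so recovery evaluations
#' match planted interactions to called regions within this margin.
#'
#' @param fmap A filtered `fragment_map`.
#' @param window Smoothing window in fragments (default 30).
#' @return Margin in bp.
#' @export
smoothing_margin <- function(fmap, window = 30) {
  vrows <- which(fmap$valid)
  if (length(vrows) < 2L) stop("need at least two valid fragments")
  pos <- (fmap$start[vrows] + fmap$end[vrows]) / 2
  (window / 2) * stats::median(diff(pos))
}

#' Interval-level recovery of planted interactions
#'
#' Compares called pCREs against the planted interactions of a simulation:
#' a planted interval counts as recovered when some pCRE overlaps it; a
#' pCRE counts as a true positive when it overlaps some planted interval.
#' `margin` pads the planted intervals on both sides before matching,
#' acknowledging the smoothing-limited resolution of the caller (see
#' [smoothing_margin()]).
#'
#' @param pcres `GRanges` of called pCREs.
#' @param truth A `sim_truth` from [simulate_4c_counts()] (or a data.frame
#'   of planted regions with 0-based `start`/`end`).
#' @param margin Padding in bp applied to planted intervals (default 0).
#' @return A list: `sensitivity` (planted intervals recovered / planted),
#'   `precision` (true-positive pCREs / called pCREs; `NA` when nothing
#'   was called), `n_called`, `n_planted`, `recovered` (logical per
#'   planted interval), `true_positive` (logical per pCRE).
#' @export
evaluate_recovery <- function(pcres, truth, margin = 0) {
  planted <- if (inherits(truth, "sim_truth")) truth$planted_regions else truth
  planted <- as.data.frame(planted)
  n_planted <- nrow(planted)
  if (n_planted == 0L) {
    return(list(sensitivity = NA_real_,
                precision = if (length(pcres)) 0 else NA_real_,
                n_called = length(pcres), n_planted = 0L,
                recovered = logical(0),
                true_positive = rep(FALSE, length(pcres))))
  }
  pg <- GenomicRanges::GRanges(
    planted$chrom,
    IRanges::IRanges(start = pmax(1, planted$start + 1 - margin),
                     end = planted$end + margin)
  )
  recovered <- GenomicRanges::countOverlaps(pg, pcres) > 0
  tp <- GenomicRanges::countOverlaps(pcres, pg) > 0
  list(sensitivity = mean(recovered),
       precision = if (length(pcres)) mean(tp) else NA_real_,
       n_called = length(pcres), n_planted = n_planted,
       recovered = recovered, true_positive = tp)
}
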