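#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet matchPattern reverseComplement oligonucleotideFrequency
#'   letterFrequency subseq
#' @importFrom BiocGenerics start end width strand
NULL

# Enzymes known to the digestion engine.  `cut_offset` is the 0-based offset
# of the cut relative to the start of the recognition motif: NlaIII leaves a
# 3' CATG overhang (cuts after the motif), DpnII a 5' GATC overhang (cuts
# before it).
.enzyme_table <- function() {
  data.frame(
    name = c("NlaIII", "DpnII"),
    motif = c("CATG", "GATC"),
    cut_offset = c(4L, 0L),
    stringsAsFactors = FALSE
  )
}

# Coerce a genome argument (FASTA path, character sequence, DNAString or
# DNAStringSet) to a single DNAString plus a chromosome name.
.as_genome <- function(genome, chrom = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- readDNAStringSet(genome)
  }
  if (is(genome, "DNAStringSet")) {
    if (length(genome) == 0L) stop("genome contains no sequences")
    if (is.null(chrom)) {
      nm <- names(genome)[1L]
      chrom <- if (is.null(nm) || !nzchar(nm)) "chrS" else sub("\\s.*$", "", nm)
    }
    genome <- genome[[1L]]
  } else if (is.character(genome)) {
    if (length(genome) != 1L) stop("supply a single genome sequence")
    genome <- DNAString(genome)
  } else if (!is(genome, "DNAString")) {
    stop("genome must be a FASTA path, character string, DNAString or DNAStringSet")
  }
  if (length(genome) == 0L) stop("genome sequence has zero length")
  list(seq = genome, chrom = if (is.null(chrom)) "chrS" else chrom)
}

#' Locate restriction sites on a DNA sequence
#'
#' Scans the forward strand for all (possibly overlapping) occurrences of an
#' enzyme's recognition motif.  CATG (NlaIII) and GATC (DpnII) are
#' palindromic, so the forward strand carries every site.  `N` bases never
#' match.
#'
#' @param seq DNA sequence: a character string, `DNAString`, `DNAStringSet`
#'   (first sequence used) or a FASTA file path.
#' @param enzyme `"NlaIII"` or `"DpnII"`.
#' @param chrom Chromosome name to attach to the sites (default taken from
#'   the FASTA header, else `"chrS"`).
#' @return A `data.frame` with columns `chrom`, `pos` (0-based start of the
#'   recognition motif) and `enzyme`.
#' @examples
#' find_sites("CATGCATG", "NlaIII")
#' @export
find_sites <- function(seq, enzyme, chrom = NULL) {
  tab <- .enzyme_table()
  i <- match(enzyme, tab$name)
  if (is.na(i)) {
    stop("unknown enzyme '", enzyme, "'; known: ",
         paste(tab$name, collapse = ", "))
  }
  g <- .as_genome(seq, chrom)
  m <- matchPattern(tab$motif[i], g$seq, fixed = TRUE)
  data.frame(
    chrom = rep(g$chrom, length(m)),
    pos = start(m) - 1L,
    enzyme = rep(enzyme, length(m)),
    stringsAsFactors = FALSE
  )
}

#' In-silico double digestion into a fragment map
#'
#' Cuts a genome with a primary and a secondary restriction enzyme and
#' returns the ordered fragment map that anchors all 4C-seq signal.  Cut
#' positions follow enzyme chemistry: NlaIII cuts at the end of its CATG
#' motif, DpnII at the start of its GATC motif.  Fragments tile
#' `[0, genome_length)` without gaps; each is labelled with the enzymes of
#' its bounding cuts (`chrom_edge` at the sequence ends).  Fragments flanked
#' by two different enzymes are candidate ("non-blind") fragments; the
#' `valid` flag is initialized to that candidacy and refined by
#' [filter_fragments()].
#'
#' @param genome Sequence as in [find_sites()].
#' @param primary,secondary Enzyme names; the primary enzyme defines the
#'   fragment ends that receive 4C reads.
#' @param chrom Optional chromosome name.
#' @return A `fragment_map`: a `data.frame` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `left_enzyme`, `right_enzyme`, `length`,
#'   `candidate`, `valid`, `end_start`, `end_end` (the primary-enzyme end
#'   sub-interval, `NA` until a single primary end is defined), with
#'   attributes `chrom`, `genome_length`, `enzymes`, `viewpoint`.
#' @export
digest <- function(genome, primary = "NlaIII", secondary = "DpnII",
                   chrom = NULL) {
  tab <- .enzyme_table()
  if (!all(c(primary, secondary) %in% tab$name)) {
    stop("unknown enzyme; known: ", paste(tab$name, collapse = ", "))
  }
  if (primary == secondary) stop("primary and secondary enzymes must differ")
  g <- .as_genome(genome, chrom)
  L <- length(g$seq)

  cuts <- data.frame(pos = integer(0), enzyme = character(0))
  for (enz in c(primary, secondary)) {
    s <- find_sites(g$seq, enz, chrom = g$chrom)
    off <- tab$cut_offset[match(enz, tab$name)]
    p <- s$pos + off
    p <- p[p >= 0L & p <= L]
    cuts <- rbind(cuts, data.frame(pos = p, enzyme = rep(enz, length(p))))
  }
  # primary enzyme takes precedence when both enzymes cut the same position
  cuts <- cuts[order(cuts$pos, match(cuts$enzyme, c(primary, secondary))), ,
               drop = FALSE]
  cuts <- cuts[!duplicated(cuts$pos), , drop = FALSE]

  # boundaries: enzyme cuts win over chromosome edges at coinciding positions
  bnd <- data.frame(pos = c(cuts$pos, 0L, L),
                    lab = c(cuts$enzyme, "chrom_edge", "chrom_edge"),
                    prio = c(rep(1L, nrow(cuts)), 2L, 2L))
  bnd <- bnd[order(bnd$pos, bnd$prio), , drop = FALSE]
  bnd <- bnd[!duplicated(bnd$pos), , drop = FALSE]
  pos2 <- bnd$pos
  lab2 <- bnd$lab

  n <- length(pos2) - 1L
  fmap <- data.frame(
    chrom = g$chrom,
    start = pos2[-length(pos2)],
    end = pos2[-1L],
    left_enzyme = lab2[-length(lab2)],
    right_enzyme = lab2[-1L],
    stringsAsFactors = FALSE
  )
  fmap$length <- fmap$end - fmap$start
  fmap$candidate <- fmap$left_enzyme != fmap$right_enzyme &
    fmap$left_enzyme %in% tab$name & fmap$right_enzyme %in% tab$name
  fmap$valid <- fmap$candidate
  mid <- fmap$start + fmap$length %/% 2L
  left_is_primary <- fmap$left_enzyme == primary
  fmap$end_start <- ifelse(fmap$candidate,
                           ifelse(left_is_primary, fmap$start, mid), NA_integer_)
  fmap$end_end <- ifelse(fmap$candidate,
                         ifelse(left_is_primary, mid, fmap$end), NA_integer_)

  structure(fmap,
            chrom = g$chrom,
            genome_length = L,
            enzymes = c(primary = primary, secondary = secondary),
            viewpoint = NA_real_,
            class = c("fragment_map", "data.frame"))
}

#' Apply the 4C fragment filters
#'
#' Marks fragments as invalid when they are blind (flanked by the same
#' enzyme), shorter than `min_len`, or overlap the viewpoint exclusion zone
#' by any amount.  No fragments are deleted; only the `valid` flag is set so
#' filtering is auditable.  The exclusion window is treated half-open
#' (`[viewpoint - exclusion, viewpoint + exclusion)`), so a fragment starting
#' exactly at `viewpoint + exclusion` is retained.
#'
#' @param fmap A `fragment_map` from [digest()].
#' @param viewpoint Viewpoint position in bp (0-based).
#' @param min_len Minimum fragment length kept, in bp; fragments strictly
#'   shorter are removed (default 40).
#' @param exclusion Half-width of the viewpoint exclusion zone in bp
#'   (default 5000).
#' @return The fragment map with `valid` flags set and the `viewpoint`
#'   attribute recorded.
#' @export
filter_fragments <- function(fmap, viewpoint, min_len = 40, exclusion = 5000) {
  stopifnot(inherits(fmap, "fragment_map"))
  if (min_len < 0 || exclusion < 0) {
    stop("min_len and exclusion must be non-negative")
  }
  if (!is.finite(viewpoint)) stop("viewpoint must be a finite position")
  in_zone <- fmap$start < viewpoint + exclusion &
    fmap$end > viewpoint - exclusion
  fmap$valid <- fmap$candidate & fmap$length >= min_len & !in_zone
  attr(fmap, "viewpoint") <- viewpoint
  fmap
}

# All primary-enzyme fragment ends (0, 1 or 2 per fragment): the half of the
# fragment abutting each primary-enzyme cut.  Used by the simulator (which
# emits counts for every primary end) and by the profile loader (which keeps
# the single primary end of each valid fragment).
.primary_ends <- function(fmap) {
  primary <- attr(fmap, "enzymes")[["primary"]]
  mid <- fmap$start + fmap$length %/% 2L
  left <- which(fmap$left_enzyme == primary & mid > fmap$start)
  right <- which(fmap$right_enzyme == primary & fmap$end > mid)
  out <- rbind(
    data.frame(frag = left, start = fmap$start[left], end = mid[left],
               side = "left", stringsAsFactors = FALSE),
    data.frame(frag = right, start = mid[right], end = fmap$end[right],
               side = "right", stringsAsFactors = FALSE)
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$chrom <- attr(fmap, "chrom")
  out
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("NlaIII/DpnII fragment map:", nrow(x), "fragments on",
      attr(x, "chrom"), sprintf("(%d bp)\n", attr(x, "genome_length")))
  cat("  valid:", sum(x$valid), " blind:", sum(!x$candidate),
      " viewpoint:", attr(x, "viewpoint"), "\n")
  invisible(x)
}

#' Write a fragment map as BED6+3
#'
#' Columns: chrom, start, end, name (`frag<N>`), score (fragment length),
#' strand (`.`), left_enzyme, right_enzyme, valid.
#'
#' @param fmap A `fragment_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fragment_map <- function(fmap, path) {
  out <- data.frame(
    chrom = fmap$chrom, start = fmap$start, end = fmap$end,
    name = paste0("frag", seq_len(nrow(fmap))), score = fmap$length,
    strand = ".", left_enzyme = fmap$left_enzyme,
    right_enzyme = fmap$right_enzyme, valid = as.integer(fmap$valid)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
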