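#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end run.  Stage
#' parameters default to the canonical analysis values: 40 bp minimum
#' fragment length, +/-5 kb viewpoint exclusion, 30-fragment smoothing and
#' coverage windows, 5 kb bins over a +/-1 Mb window, 2.5% viewpoint
#' fraction, 40 bp pCRE merge gap, 10,000 permutations, 100 bp rebinning
#' and oligomer lengths 6 and 7.  Unknown keys are rejected.
#'
#' @param x A named list (e.g. parsed from YAML) or a YAML file path; may
#'   contain `seed`, `viewpoint` (`list(chrom, pos)`), `params` (any subset
#'   of the defaults below), `expressing`, `inputs` (paths: `genome`,
#'   `counts` as cell-line -> replicate bedGraph paths, `peaks` manifest,
#'   `genes`) and/or `simulate` (a `sim` override list plus per-cell-line
#'   `planted` interaction lists and a `chip` design).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(
    seed = 1L,
    viewpoint = list(chrom = "chrS", pos = 1e6),
    expressing = NULL,
    params = list(min_len = 40, exclusion = 5000, window = 30,
                  bin = 5000, span = 1e6, target_total = 1e6,
                  vp_frac = 0.025, snr_k = 2, coverage_quantile = 0.75,
                  merge_gap = 40, n_perm = 10000, corr_width = 100,
                  k = c(6, 7), motif_evalue = 1),
    inputs = NULL,
    simulate = NULL
  )
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  if (!is.null(x$params)) {
    bad <- setdiff(names(x$params), names(defaults$params))
    if (length(bad)) stop("unknown params key(s): ", paste(bad, collapse = ", "))
    cfg$params <- utils::modifyList(defaults$params, x$params)
  }
  if (is.null(cfg$inputs) && is.null(cfg$simulate)) {
    stop("config needs either 'inputs' or 'simulate'")
  }
  structure(cfg, class = "pipeline_config")
}

# Deterministic per-stage substream seed derived from the run seed.
.stage_seed <- function(seed, stage) {
  stages <- c("genome", "counts", "chip", "call", "enrich", "correlate",
              "motif")
  i <- match(stage, stages)
  as.integer((as.numeric(seed) * 48271 + i * 100003) %% 2147483647)
}

#' Run the full 4C analysis pipeline
#'
#' Orchestrates every stage on either simulated or file-based inputs:
#' genome and fragment map, per-replicate viewpoint profiles, background
#' fitting and interaction calling per cell line, pCRE merging,
#' shared/gained/lost classification against the expressing line,
#' permutation enrichment of gained/lost pCREs against peak sets,
#' 100 bp-rebinned Pearson correlation, and k-mer motif analysis of the
#' top gained pCREs.  Every artifact is written under `outdir` together
#' with a JSON manifest (config hash, seed, package version), and reruns
#' with the same config and seed are bit-identical.
#'
#' @param config A [pipeline_config()] (or the list/path it accepts).
#' @param outdir Output directory (created; stage subdirectories inside).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with the fragment map, per-cell-line pCREs,
#'   classification, enrichment tables, correlation matrix and motif
#'   table.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  p <- cfg$params
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("map", "profiles", "pcres", "classes", "enrichment",
              "correlation", "motifs")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  log <- function(...) message("[fourcre] ", ...)

  vp <- cfg$viewpoint$pos
  sim_mode <- !is.null(cfg$simulate)

  # ---- genome + fragment map ----
  if (sim_mode) {
    sim_over <- cfg$simulate$sim
    if (is.null(sim_over)) sim_over <- list()
    sim_over$seed <- .stage_seed(cfg$seed, "genome")
    if (is.null(sim_over$viewpoint_pos)) sim_over$viewpoint_pos <- vp
    if (is.null(sim_over$chrom)) sim_over$chrom <- cfg$viewpoint$chrom
    scfg <- do.call(sim_config, sim_over)
    log("simulating genome (", scfg$genome_length, " bp)")
    genome <- simulate_genome(scfg, fasta = file.path(outdir, "map", "genome.fa"))
  } else {
    genome <- readDNAStringSet(cfg$inputs$genome)
  }
  fmap <- digest(genome, chrom = cfg$viewpoint$chrom)
  fmap <- filter_fragments(fmap, vp, min_len = p$min_len,
                           exclusion = p$exclusion)
  write_fragment_map(fmap, file.path(outdir, "map", "fragment_map.bed"))
  log(sum(fmap$valid), " valid fragments of ", nrow(fmap))

  # ---- counts per cell line ----
  if (sim_mode) {
    lines <- cfg$simulate$cell_lines
    if (is.null(lines)) stop("simulate config needs 'cell_lines'")
    counts <- list()
    for (i in seq_along(lines)) {
      nm <- names(lines)[i]
      scfg_i <- scfg
      scfg_i$planted_interactions <- lines[[i]]$planted
      if (is.null(scfg_i$planted_interactions)) scfg_i$planted_interactions <- list()
      scfg_i$seed <- .stage_seed(cfg$seed, "counts") + i
      sim <- simulate_4c_counts(fmap, scfg_i,
                                outdir = file.path(outdir, "profiles", nm))
      counts[[nm]] <- sim$counts
    }
  } else {
    counts <- lapply(cfg$inputs$counts, function(paths) {
      lapply(paths, read_bedgraph)
    })
  }
  for (nm in names(counts)) {
    if (length(counts[[nm]]) < 2L) {
      stop("cell line '", nm, "' has fewer than two replicates; ",
           "interactions must appear in every replicate")
    }
  }

  # ---- profiles + calling per cell line ----
  pcres <- list()
  calls <- list()
  ccfg <- caller_config(viewpoint_fraction = p$vp_frac, snr_k = p$snr_k,
                        coverage_window = p$window,
                        coverage_quantile = p$coverage_quantile,
                        merge_gap = p$merge_gap, flank = p$span)
  for (nm in names(counts)) {
    profs <- list()
    binned <- list()
    for (r in seq_along(counts[[nm]])) {
      pr <- prepare_profile(counts[[nm]][[r]], fmap,
                            replicate = paste0(nm, "_rep", r),
                            target_total = p$target_total,
                            window = p$window)
      profs[[r]] <- pr
      binned[[r]] <- bin_counts(pr, bin = p$bin, span = p$span)
      write_bedgraph(data.frame(chrom = pr$fmap_chrom, start = pr$end_start,
                                end = pr$end_end, count = pr$smoothed),
                     file.path(outdir, "profiles",
                               sprintf("%s_rep%d_smoothed.bedGraph", nm, r)))
    }
    if (length(binned) >= 2L) {
      rc <- replicate_correlation(binned[[1L]], binned[[2L]])
      log(nm, " replicate correlation r = ", round(rc$r, 3))
    }
    cl <- call_fragments(profs, config = ccfg)
    calls[[nm]] <- cl
    pcres[[nm]] <- merge_to_pcres(cl, merge_gap = p$merge_gap, cell_line = nm)
    .write_pcre_bed(pcres[[nm]],
                    file.path(outdir, "pcres", paste0(nm, "_pcres.bed")))
    log(nm, ": ", sum(cl$significant), " significant fragments -> ",
        length(pcres[[nm]]), " pCREs")
  }

  # ---- classification ----
  expressing <- cfg$expressing
  if (is.null(expressing)) expressing <- names(pcres)[1L]
  baselines <- pcres[setdiff(names(pcres), expressing)]
  classified <- NULL
  if (length(baselines)) {
    classified <- classify_pcres(pcres[[expressing]], baselines)
    cls_gr <- classified$regions
    dc <- distance_class(cls_gr, viewpoint = vp,
                         viewpoint_chrom = cfg$viewpoint$chrom)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(cls_gr)),
                     start = start(cls_gr) - 1L, end = end(cls_gr),
                     class = cls_gr$class, distance_class = as.character(dc))
    utils::write.table(df, file.path(outdir, "classes", "pcre_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log("classes: ", paste(names(classified$counts), classified$counts,
                           collapse = ", "))
  }

  # ---- peak sets ----
  peaks <- list()
  ref_info <- NULL
  win <- c(max(0, vp - p$span), min(attr(fmap, "genome_length"), vp + p$span))
  if (sim_mode && !is.null(cfg$simulate$chip) && !is.null(classified)) {
    chip <- cfg$simulate$chip
    qsets <- list(
      gained = classified$regions[classified$regions$class == "gained"],
      lost = classified$regions[classified$regions$class == "lost"]
    )
    k2 <- 0L
    for (i in seq_along(chip)) {
      des <- chip[[i]]
      k2 <- k2 + 1L
      target <- if (!is.null(des$target)) des$target else "gained"
      sc <- simulate_chip_peaks(
        qsets[[target]], win,
        n_peaks = if (!is.null(des$n_peaks)) des$n_peaks else 200,
        overlap_fraction = des$overlap_fraction,
        seed = .stage_seed(cfg$seed, "chip") + k2,
        chrom = cfg$viewpoint$chrom
      )
      peaks[[names(chip)[i]]] <- sc$peaks
    }
    ref_info <- data.frame(mark = names(chip), cell = "sim",
                           replicate = "rep1", stringsAsFactors = FALSE)
  } else if (!sim_mode && !is.null(cfg$inputs$peaks)) {
    man <- cfg$inputs$peaks
    if (is.character(man)) {
      man <- utils::read.table(man, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    }
    peaks <- lapply(man$path, read_bed)
    names(peaks) <- paste(man$mark, man$cell, man$replicate, sep = ".")
    ref_info <- man[, c("mark", "cell", "replicate")]
  }

  # ---- enrichment ----
  enr <- NULL
  if (length(peaks) && !is.null(classified)) {
    queries <- list(
      gained = classified$regions[classified$regions$class == "gained"],
      lost = classified$regions[classified$regions$class == "lost"]
    )
    queries <- queries[vapply(queries, length, integer(1)) > 0]
    if (length(queries)) {
      enr <- enrichment_table(queries, peaks, ref_info, universe = win,
                              n = p$n_perm,
                              seed = .stage_seed(cfg$seed, "enrich"))
      utils::write.table(enr$tests,
                         file.path(outdir, "enrichment", "tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(enr$summary,
                         file.path(outdir, "enrichment", "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # ---- correlation ----
  corr <- NULL
  corr_samples <- c(
    lapply(pcres, function(g) {
      S4Vectors::mcols(g)$score <- g$peak_signal
      g
    }),
    peaks
  )
  corr_samples <- corr_samples[vapply(corr_samples, length, integer(1)) > 1]
  if (length(corr_samples) >= 2L) {
    bm <- rebin(corr_samples, chrom_length = attr(fmap, "genome_length"),
                width = p$corr_width)
    bm <- drop_empty(bm)
    corr <- pearson_matrix(bm)
    utils::write.table(round(corr$r, 6),
                       file.path(outdir, "correlation", "pearson.tsv"),
                       sep = "\t", quote = FALSE)
    log("correlation over ", nrow(bm$mat), " retained bins (sparsity ",
        round(bm$sparsity, 3), ")")
  }

  # ---- motifs ----
  motifs <- NULL
  if (!is.null(classified)) {
    gained <- classified$regions[classified$regions$class == "gained"]
    if (length(gained)) {
      sel <- gained[order(-GenomicRanges::width(gained))]
      sel <- sel[seq_len(min(2L, length(sel)))]
      seqs <- subseq(rep(genome[1L], length(sel)),
                     start = start(sel), end = end(sel))
      tabs <- lapply(p$k, function(kk) {
        oligo_enrichment(count_oligos(seqs, kk))
      })
      motifs <- do.call(rbind, lapply(tabs, as.data.frame))
      utils::write.table(motifs,
                         file.path(outdir, "motifs", "oligo_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sig <- motifs[motifs$evalue < p$motif_evalue, , drop = FALSE]
      if (nrow(sig)) {
        mats <- assemble_matrices(sig$oligo, weights = sig$observed)
        write_meme(mats, file.path(outdir, "motifs", "motifs.meme"))
        write_transfac(mats, file.path(outdir, "motifs", "motifs.transfac"))
      }
    }
  }

  # ---- manifest ----
  manifest <- list(
    package = "fourcre",
    version = as.character(utils::packageVersion("fourcre")),
    seed = cfg$seed,
    config_hash = .config_hash(cfg),
    config = unclass(cfg)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(fmap = fmap, calls = calls, pcres = pcres,
                 classified = classified, enrichment = enr,
                 correlation = corr, motifs = motifs))
}

.config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(cfg), tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

.write_pcre_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    name = if (length(gr)) paste0(gr$cell_line, "_pcre", seq_along(gr)) else character(0),
    score = if (length(gr)) round(gr$peak_signal, 3) else numeric(0),
    strand = rep(".", length(gr))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions as GRanges
#'
#' Uses `rtracklayer` for standard BED parsing.
#'
#' @param path BED file path.
#' @return A `GRanges` (with `score` when present).
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a GRanges as BED6
#'
#' @param gr A `GRanges`, optionally with `score` and `name` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
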