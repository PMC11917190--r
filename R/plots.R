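#' Plot a viewpoint profile with its fitted background
#'
#' @param profile A smoothed `vp_profile`.
#' @param fit Optional `background_fit` drawn over the profile.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_profile <- function(profile, fit = NULL, ...) {
  stopifnot(inherits(profile, "vp_profile"))
  y <- if (!is.null(profile$smoothed)) profile$smoothed else profile$raw
  graphics::plot(profile$distance / 1e3, y, type = "l",
                 xlab = "distance from viewpoint (kb)",
                 ylab = "smoothed signal", ...)
  if (!is.null(fit)) {
    graphics::lines(profile$distance / 1e3, fit$b, col = "red", lwd = 2)
  }
  graphics::abline(v = 0, lty = 3)
  invisible(NULL)
}

#' Bar plot of proportional overlap with significance shading
#'
#' Bars show the mean proportional overlap of each query class with each
#' mark; non-significant bars (mean FDR at or above `alpha`) are drawn in a
#' faint tint.
#'
#' @param summary The `summary` table from [enrichment_table()].
#' @param alpha FDR significance threshold (default 0.05).
#' @return Invisibly, `NULL`.
#' @export
plot_enrichment <- function(summary, alpha = 0.05) {
  lab <- paste(summary$query, summary$mark, summary$cell, sep = "\n")
  sig <- summary$mean_fdr < alpha
  cols <- ifelse(sig, "firebrick", grDevices::adjustcolor("firebrick", 0.3))
  graphics::barplot(summary$mean_prop_overlap, names.arg = lab,
                    col = cols, las = 2, cex.names = 0.7,
                    ylab = "proportional overlap")
  invisible(NULL)
}

#' Heatmap of the pairwise Pearson matrix
#'
#' Uses `pheatmap` when installed, otherwise [graphics::image()] in the
#' clustering order.
#'
#' @param pm Result of [pearson_matrix()].
#' @return Invisibly, `NULL`.
#' @export
plot_correlation_heatmap <- function(pm) {
  r <- pm$r[pm$order, pm$order]
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(r, cluster_rows = FALSE, cluster_cols = FALSE)
  } else {
    graphics::image(seq_len(nrow(r)), seq_len(ncol(r)), r,
                    xlab = "", ylab = "", axes = FALSE, main = "Pearson r")
    graphics::axis(1, seq_len(nrow(r)), rownames(r), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(ncol(r)), colnames(r), las = 2, cex.axis = 0.7)
  }
  invisible(NULL)
}

#' Per-class density curves of pCRE distances
#'
#' @param densities Named list from [distance_density()].
#' @return Invisibly, `NULL`.
#' @export
plot_distance_density <- function(densities) {
  if (!length(densities)) stop("no densities to plot")
  xr <- range(unlist(lapply(densities, `[[`, "x")))
  yr <- range(unlist(lapply(densities, `[[`, "y")))
  cols <- stats::setNames(grDevices::hcl.colors(length(densities), "Dark 3"),
                          names(densities))
  graphics::plot(NA, xlim = xr / 1e3, ylim = yr,
                 xlab = "|distance| from viewpoint (kb)", ylab = "density")
  for (nm in names(densities)) {
    graphics::lines(densities[[nm]]$x / 1e3, densities[[nm]]$y,
                    col = cols[nm], lwd = 2)
  }
  graphics::legend("topright", legend = names(densities), col = cols, lwd = 2)
  invisible(NULL)
}
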