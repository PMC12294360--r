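.needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to use the plotting helpers", call. = FALSE)
}

#' Diagnostic plots for codon usage analyses
#'
#' ggplot2-based views of the standard diagnostics: the neutrality plot
#' (GC12 vs GC3 with the fitted line and the identity), the ENC-GC3 plot
#' with the expected-ENC curve, the PR2 plot with its parity midlines,
#' the CAI-ENC scatter, and a tile view of the cross-species RSCU
#' heatmap matrix.
#'
#' @param x For `plotNeutrality` a [neutralityFit()] result; for
#'   `plotEncGc3`, `plotPr2`, `plotCaiEnc` a gene statistics data.frame
#'   (or [CodonUsageSet-class]); for `plotRscuHeatmap` an
#'   [rscuHeatmapMatrix()] result.
#' @return A ggplot object.
#' @name cub-plots
NULL

#' @rdname cub-plots
#' @export
plotNeutrality <- function(x) {
  .needGgplot()
  stopifnot(inherits(x, "neutrality_fit"))
  ggplot2::ggplot(x$table, ggplot2::aes(gc3, gc12)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
      colour = "grey50") +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
      colour = "firebrick") +
    ggplot2::labs(x = "GC3", y = "GC12",
      title = sprintf("Neutrality plot (slope %.3f, r %.3f)",
        x$slope, x$r)) +
    ggplot2::theme_minimal()
}

#' @rdname cub-plots
#' @export
plotEncGc3 <- function(x) {
  .needGgplot()
  if (is(x, "CodonUsageSet")) x <- geneStats(x)
  curve <- data.frame(gc3s = seq(0.01, 0.99, by = 0.01))
  curve$enc <- encExpected(curve$gc3s)
  ggplot2::ggplot(x, ggplot2::aes(gc3s, encObs)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve,
      ggplot2::aes(gc3s, enc), colour = "firebrick") +
    ggplot2::labs(x = "GC3s", y = "ENC") +
    ggplot2::theme_minimal()
}

#' @rdname cub-plots
#' @export
plotPr2 <- function(x) {
  .needGgplot()
  if (is(x, "CodonUsageSet")) x <- geneStats(x)
  ggplot2::ggplot(x, ggplot2::aes(pr2x, pr2y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "G3/(G3+C3)", y = "A3/(A3+U3)") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @rdname cub-plots
#' @export
plotCaiEnc <- function(x) {
  .needGgplot()
  if (is(x, "CodonUsageSet")) x <- geneStats(x)
  ggplot2::ggplot(x, ggplot2::aes(cai, encObs)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "CAI", y = "ENC") +
    ggplot2::theme_minimal()
}

#' @rdname cub-plots
#' @export
plotRscuHeatmap <- function(x) {
  .needGgplot()
  stopifnot(inherits(x, "rscu_heatmap"))
  v <- x$values
  df <- data.frame(
    row = rep(rownames(v), ncol(v)),
    col = rep(colnames(v), each = nrow(v)),
    rscu = as.vector(v),
    label = as.vector(x$labels)
  )
  df$row <- factor(df$row, levels = rev(rownames(v)))
  df$col <- factor(df$col, levels = colnames(v))
  ggplot2::ggplot(df, ggplot2::aes(col, row,
    fill = rscu)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = label), size = 2) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
      mid = "white", high = "firebrick", na.value = "grey90") +
    ggplot2::labs(x = "species . third base", y = "first two bases",
      fill = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
      vjust = 0.5, hjust = 1))
}

utils::globalVariables(c("gc3", "gc12", "gc3s", "encObs", "enc",
  "pr2x", "pr2y", "cai", "col", "row", "rscu", "label"))
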