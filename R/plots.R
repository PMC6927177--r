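
#' Plot the enrichment PCA diagnostic
#'
#' @param pca output of [enrichment_pca()]
#' @param colour_by optional vector (length = samples) to colour points by,
#'   e.g. group or batch
#' @return a ggplot
#' @export
plot_enrichment_pca <- function(pca, colour_by = NULL) {
  ve <- attr(pca, "var_explained")
  lab <- function(i) {
    if (is.null(ve)) paste0("PC", i)
    else sprintf("PC%d (%.0f%%)", i, 100 * ve[i])
  }
  df <- pca
  if (!is.null(colour_by)) df$colour <- colour_by
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_bw()
  if (is.null(colour_by)) p + ggplot2::geom_point(size = 2)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), size = 2) +
    ggplot2::labs(colour = NULL)
}

#' Volcano plot of a differential methylation result
#'
#' @param object a `merip_dm` tibble
#' @param fdr_cutoff highlight bins below this BH cutoff
#' @param ... unused
#' @return a ggplot
#' @method autoplot merip_dm
#' @export
autoplot.merip_dm <- function(object, fdr_cutoff = 0.1, ...) {
  df <- mutate(as_tibble(object),
               significant = !is.na(.data$padj) & .data$padj < fdr_cutoff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc,
                                   y = -log10(pmax(.data$p.value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log fold change (beta0)", y = "-log10 p",
                  colour = paste0("padj < ", fdr_cutoff)) +
    ggplot2::theme_bw()
}

#' Sensitivity / FDR across sample sizes
#'
#' @param object a `merip_benchmark` tibble from [sample_size_sweep()]
#' @param ... unused
#' @return a ggplot of sensitivity against empirical FDR, coloured by
#'   sample size
#' @method autoplot merip_benchmark
#' @export
autoplot.merip_benchmark <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$empirical_fdr,
                                       y = .data$sensitivity,
                                       colour = factor(.data$n))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$cutoff[1], linetype = "dashed") +
    ggplot2::labs(x = "empirical FDR", y = "sensitivity",
                  colour = "samples") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
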