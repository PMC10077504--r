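# ggplot2 views of the main result types.

#' Manhattan plot of association or meta-analysis results
#'
#' @param stats Tibble with `chrom`, `pos` and a P-value column (`p` or
#'   `p_wald`).
#' @param threshold Optional significance threshold drawn as a line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(stats, threshold = NULL) {
  p_col <- if ("p" %in% names(stats)) "p" else "p_wald"
  df <- stats |>
    mutate(logp = -log10(.data[[p_col]]),
           chrom = factor(.data$chrom, levels = unique(.data$chrom)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$logp,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](P))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   linetype = "dashed")
  }
  gg
}

#' Quantile-quantile plot of P-values with the genomic-control lambda
#'
#' @param pvalues P-values in (0, 1].
#' @return A ggplot object annotated with lambda-GC.
#' @export
plot_qq <- function(pvalues) {
  pvalues <- sort(pvalues[!is.na(pvalues)])
  n <- length(pvalues)
  df <- tibble(expected = -log10((seq_len(n) - 0.5) / n),
               observed = -log10(pvalues))
  lam <- lambda_gc(pvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::annotate("text", x = 0.5, y = max(df$observed),
                      label = sprintf("lambda[GC] == %.3f", lam),
                      parse = TRUE, hjust = 0) +
    ggplot2::labs(x = expression(Expected - log[10](P)),
                  y = expression(Observed - log[10](P))) +
    ggplot2::theme_minimal()
}

#' Forest plot of MR estimates
#'
#' @param results Tibble with `protein`, `trait`, `beta`, `se` and
#'   optionally `p_fdr`.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(results) {
  df <- results |>
    mutate(label = paste(.data$protein, "→", .data$trait),
           lo = .data$beta - 1.96 * .data$se,
           hi = .data$beta + 1.96 * .data$se)
  ggplot2::ggplot(df, ggplot2::aes(.data$beta, .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "causal effect (outcome units per SD exposure)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
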