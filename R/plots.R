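# ggplot2 autoplot methods for the result classes.

#' Plot a RIP enrichment result
#'
#' Volcano-style view: log2 fold change against `-log10(p)` with selected
#' targets highlighted, or the Vfactor against the mean count.
#'
#' @param object A [rip_enrichment()] result.
#' @param type `"volcano"` (default) or `"vfactor"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.rip_result <- function(object, type = c("volcano", "vfactor"),
                                ...) {
  type <- match.arg(type)
  df <- tidy(object)
  df$status <- ifelse(df$selected, "selected", "other")
  if (type == "volcano") {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$log2fc, y = -log10(.data$p), colour = .data$status
    )) +
      ggplot2::labs(x = "log2 fold change (IP / input)",
                    y = expression(-log[10] ~ p))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$base_mean, y = .data$vfactor, colour = .data$status
    )) +
      ggplot2::scale_x_log10() +
      ggplot2::geom_hline(
        yintercept = attr(object, "params")$vfactor_threshold,
        linetype = "dashed"
      ) +
      ggplot2::labs(x = "mean normalized count", y = "Vfactor")
  }
  p +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(selected = "#d95f02", other = "grey50"), name = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot an interactor volcano
#'
#' log2 enrichment against `-log10(p)`, with the significance classes
#' colored and the s0/FDR cutoff reported in the subtitle.
#'
#' @param object A [call_interactors()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.volcano_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_enrichment, y = -log10(.data$p), colour = .data$class
  )) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(enriched = "#d95f02", depleted = "#7570b3",
                 ns = "grey60"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "log2 enrichment (bait - control)",
      y = expression(-log[10] ~ p),
      subtitle = sprintf("|d| cutoff %.2f at FDR %g, s0 = %g",
                         attr(object, "cutoff"),
                         attr(object, "params")$fdr,
                         attr(object, "params")$s0)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a category enrichment result
#'
#' Observed versus expected overlap per category, sized by significance.
#'
#' @param object A [category_enrichment()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.enrich_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$category, -.data$p),
    y = .data$fraction
  )) +
    ggplot2::geom_col(ggplot2::aes(fill = -log10(.data$padj))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected / .data$n),
                        shape = 4) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of query in category",
                  fill = expression(-log[10] ~ padj)) +
    ggplot2::theme_minimal()
}
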