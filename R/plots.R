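# ggplot2 views of the three result types: the per-exon contrast with its
# bootstrap band, signature-score distributions by deletion group, and the
# rescaled TT-seq exon profile.

#' Plot a per-exon deleted-vs-wild-type contrast
#'
#' @param contrast Tibble from [exon_contrast()].
#' @return A ggplot object: per-exon mean difference with its percentile
#'   bootstrap band.
#' @export
plot_exon_contrast <- function(contrast) {
  p <- ggplot2::ggplot(contrast,
                       ggplot2::aes(x = .data$exon_index, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::geom_point(colour = "#2166AC") +
    ggplot2::scale_x_continuous(breaks = contrast$exon_index) +
    ggplot2::labs(x = "Exon (transcription order)",
                  y = "Mean difference (deleted - wild-type)",
                  title = "Per-exon expression contrast") +
    ggplot2::theme_minimal()
  if (!all(is.na(contrast$lower))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.2, fill = "#2166AC")
  }
  p
}

#' @export
autoplot.fx_exon_contrast <- function(object, ...) plot_exon_contrast(object)

#' Plot signature scores by deletion group
#'
#' @param scores Score table with columns `score` and `group` (e.g.
#'   [score_signature()] joined with [stratify_by_element()]).
#' @return A ggplot box plot of scores per group.
#' @export
plot_signature_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$group, y = .data$score,
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 21, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("#B2182B", "grey80")) +
    ggplot2::labs(x = NULL, y = "Signature score (mean z)",
                  title = "Instability signature by deletion status") +
    ggplot2::theme_minimal()
}

#' Plot a rescaled exon expression profile
#'
#' @param profile Tibble from [ttseq_exon_profile()].
#' @param element_after Optional exon index after which the intragenic
#'   element lies; drawn as a vertical marker.
#' @return A ggplot object.
#' @export
plot_exon_profile <- function(profile, element_after = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$exon_index,
                                             y = .data$rescaled)) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::scale_x_continuous(breaks = profile$exon_index) +
    ggplot2::labs(x = "Exon (transcription order)",
                  y = "Rescaled expression [0, 1]",
                  title = "Nascent-transcription exon profile") +
    ggplot2::theme_minimal()
  if (!is.null(element_after)) {
    p <- p + ggplot2::geom_vline(xintercept = element_after + 0.5,
                                 linetype = "dotted", colour = "#B2182B")
  }
  p
}

#' @export
autoplot.fx_exon_profile <- function(object, ...) plot_exon_profile(object)
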