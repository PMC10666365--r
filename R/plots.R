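#' Plot a perturbation screen as an EMT dot-interval chart
#'
#' Interventions on the y axis, EMT level on the x axis; intervals from
#' unknown markers are drawn as segments. The baseline level, if a
#' baseline row is present, is marked with a dashed line.
#'
#' @param screen A screen tibble from [single_screen()],
#'   [double_screen()] or [baseline_response()] (rows may be
#'   concatenated).
#' @param top Show only the `top` lowest-EMT interventions (default 20).
#' @return A ggplot object.
#' @export
plot_screen <- function(screen, top = 20) {
  df <- utils::head(screen, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$emt_lo + .data$emt_hi) / 2,
    y = stats::reorder(.data$intervention, -.data$emt_lo))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$emt_lo,
                                       xend = .data$emt_hi,
                                       yend = stats::reorder(
                                         .data$intervention,
                                         -.data$emt_lo)),
                          linewidth = 2, alpha = 0.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(limits = c(0, 4),
                                breaks = 0:4) +
    ggplot2::labs(x = "EMT level", y = NULL,
                  title = "In-silico perturbation screen") +
    ggplot2::theme_minimal()
}

#' Plot motif scores across weighting scenarios
#'
#' One line per motif across scenarios; the motifs selected in every
#' scenario stand out as consistently high lines.
#'
#' @param scores Score tibble from [score_motifs()].
#' @param highlight Optional motif ids to color.
#' @return A ggplot object.
#' @export
plot_motif_scores <- function(scores, highlight = NULL) {
  scores$highlighted <- if (is.null(highlight)) FALSE else
    scores$motif_id %in% highlight
  ggplot2::ggplot(scores, ggplot2::aes(
    x = .data$scenario, y = .data$score, group = .data$motif_id,
    color = .data$highlighted)) +
    ggplot2::geom_line(alpha = 0.5, show.legend = !is.null(highlight)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "weighting scenario", y = "ranking score",
                  color = "highlighted") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
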