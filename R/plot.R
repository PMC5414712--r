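#' Plot the genomic layout of detected repeats
#'
#' Draws each repeat as a pair of arm segments joined by a thin spacer
#' line, stacked along the y axis, coloured by the recombinogenicity call.
#'
#' @param object An `lir_result` (or any LIR tibble with coordinates).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lir_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  if (!"recombinogenic" %in% names(d)) {
    d <- classify_recombinogenic(d)
  }
  if (nrow(d) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No long inverted repeats detected") +
             ggplot2::theme_minimal())
  }
  d <- d |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::mutate(y = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$left_end,
                                       xend = .data$right_start,
                                       y = .data$y, yend = .data$y),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$left_start,
                                       xend = .data$left_end,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$recombinogenic),
                          linewidth = 2) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$right_start,
                                       xend = .data$right_end,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$recombinogenic),
                          linewidth = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$seq_id), scales = "free") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  colour = "recombinogenic") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Stem length versus spacer size
#'
#' Scatter of the two geometric determinants of recombinogenicity, with
#' the `delta = 1` boundary (stem length equal to spacer) drawn as a
#' reference line. Perfect repeats above the line are called
#' recombinogenic.
#'
#' @param lirs An LIR tibble with `repeat_length`, `spacer` and (optionally)
#'   `recombinogenic` columns.
#' @return A ggplot object.
#' @export
plot_delta_spacer <- function(lirs) {
  d <- tibble::as_tibble(lirs)
  if (!"recombinogenic" %in% names(d)) {
    d <- classify_recombinogenic(d)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$spacer + 1,
                                  y = .data$repeat_length,
                                  colour = .data$recombinogenic)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "spacer + 1 (bp)", y = "stem length (bp)",
                  colour = "recombinogenic") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
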