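#' Plot a copy-number spectrum
#'
#' Bar chart of reads per copy-number class; multimodality is the visual
#' signature of structural heteroplasmy.
#'
#' @param object A `copy_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.copy_spectrum <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$copy_number), y = .data$n_reads)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "gene copies per spanning read",
      y = "reads",
      title = attr(object, "sample") %||% NULL,
      subtitle = sprintf("%d anchor-spanning reads", attr(object, "n_spanning"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a block decomposition as a linear gene map
#'
#' Blocks are drawn along the target with strand shown by track: forward
#' blocks above the axis, reverse blocks (e.g. an inversion) below.
#'
#' @param object A `block_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.block_decomposition <- function(object, ...) {
  b <- object$blocks
  if (nrow(b) == 0) abort("empty decomposition")
  b$y <- ifelse(b$strand == "+", 1, -1)
  b$class <- dplyr::case_when(
    grepl("^trn", b$gene) ~ "tRNA",
    b$gene %in% c("12S", "16S") ~ "rRNA",
    b$gene == "CR" ~ "control region",
    TRUE ~ "protein coding"
  )
  ggplot2::ggplot(b) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = .data$y * 0.2, ymax = .data$y * 1,
      fill = .data$class
    ), colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::scale_y_continuous(breaks = c(-0.6, 0.6), labels = c("-", "+"),
                                limits = c(-1.2, 1.2)) +
    ggplot2::labs(x = "target position (nt)", y = "strand", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot tandem repeats along a sequence
#'
#' @param repeats A [find_tandem_repeats()] result.
#' @param seq_length Optional sequence length for the x axis.
#' @return A ggplot object.
#' @export
plot_repeats <- function(repeats, seq_length = NULL) {
  r <- as_tibble(repeats)
  if (nrow(r) == 0) abort("no repeats to plot")
  r$label <- sprintf("%d bp x %.1f", r$period, r$copies)
  p <- ggplot2::ggplot(r) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$end,
      y = factor(.data$period), yend = factor(.data$period),
      colour = .data$identity
    ), linewidth = 4) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start + .data$end) / 2, y = factor(.data$period),
      label = .data$label
    ), vjust = -1, size = 3) +
    ggplot2::labs(x = "position (nt)", y = "period (nt)", colour = "identity") +
    ggplot2::theme_minimal()
  if (!is.null(seq_length)) p <- p + ggplot2::xlim(1, seq_length)
  p
}
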