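# ggplot2 displays for the main result types.

#' Plot a content matrix
#'
#' Taxa-by-element tile plot with the cell glyphs, in the style of published
#' organellar gene/intron content figures.
#'
#' @param object A `content_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot content_matrix
#' @export
autoplot.content_matrix <- function(object, ...) {
  elements <- attr(object, "element_order") %||% unique(object$element)
  taxa <- unique(object$taxon)
  df <- as_tibble(object)
  df$element <- factor(df$element, levels = elements)
  df$taxon <- factor(df$taxon, levels = rev(taxa))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$element, y = .data$taxon,
                                   fill = .data$call)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$glyph), size = 3) +
    ggplot2::scale_fill_manual(values = c(
      present = "white", tentative = "lightyellow", pseudogene = "grey80",
      lost = "grey60", intron_host_lost = "grey90", remnant = "grey85")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1),
                   legend.position = "bottom") +
    ggplot2::labs(x = NULL, y = NULL, fill = "call")
}

#' Plot a coverage track
#'
#' Windowed mean depth along the genome, optionally overlaying feature
#' intervals (for example repeats and plastid-derived insertions) to show
#' their correlation with coverage depth.
#'
#' @param object A coverage track tibble.
#' @param features Optional tibble with `start`, `end` and a `kind` column.
#' @param window Window size (bp) for mean smoothing.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coverage_track
#' @export
autoplot.coverage_track <- function(object, features = NULL, window = 500L,
                                    ...) {
  df <- as_tibble(object)
  df$bin <- df$pos %/% window
  binned <- df |>
    group_by(.data$bin) |>
    summarise(pos = min(.data$pos), depth = mean(.data$depth),
              .groups = "drop")
  p <- ggplot2::ggplot(binned, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "genome position (bp)", y = "depth of coverage")
  if (!is.null(features) && nrow(features)) {
    p <- p + ggplot2::geom_rect(
      data = features,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = 0, fill = .data$kind),
      inherit.aes = FALSE, alpha = 0.8)
  }
  p
}

#' Plot a repeat size-class summary
#'
#' @param summary One-row tibble from [summarize_repeats()].
#' @return A ggplot bar chart of per-class repeat counts.
#' @export
plot_repeat_classes <- function(summary) {
  df <- tibble(class = factor(c("small", "intermediate", "large"),
                              levels = c("small", "intermediate", "large")),
               n = c(summary$n_small, summary$n_intermediate,
                     summary$n_large))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "repeat size class", y = "pairs")
}
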