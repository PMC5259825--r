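#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a merged spectrum
#'
#' Stick plot of the merged, scored peak list: position is the charge-1
#' m/z, height the accumulated significance score, colour the source mode.
#'
#' @param object A `novopair_merged` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot novopair_merged
#' @export
autoplot.novopair_merged <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                   y = 0, yend = .data$ss,
                                   colour = .data$mode)) +
    ggplot2::geom_segment(linewidth = 0.8) +
    ggplot2::labs(
      x = "charge-1 m/z", y = "significance score ss",
      colour = "source",
      title = sprintf("Merged spectrum (m_p = %.3f)",
                      attr(object, "m_p") %||% NA_real_)
    ) +
    ggplot2::theme_minimal()
}

#' Plot ranked candidates
#'
#' Bar chart of candidate scores by rank, faceted by pair when the table
#' covers several pairs.
#'
#' @param object A `novopair_candidates` tibble or [run_pipeline()] output.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot novopair_candidates
#' @export
autoplot.novopair_candidates <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank),
                                        y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$sequence),
                       angle = 90, hjust = 1.05, size = 3,
                       colour = "white") +
    ggplot2::labs(x = "rank", y = "candidate score cs",
                  title = "Ranked peptide candidates") +
    ggplot2::theme_minimal()
  if ("pair_id" %in% names(df) && length(unique(df$pair_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~pair_id, scales = "free_y")
  }
  p
}
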