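#' Plot a repeat-length histogram
#'
#' Column chart of (optionally normalized) read counts per repeat index,
#' the standard display of amplicon CAG-sizing data. The progenitor allele
#' bin can be highlighted.
#'
#' @param object A `repeat_histogram` (or [size_sample()] result).
#' @param normalize Scale counts to 1,000 reads before plotting.
#' @param M Optional progenitor length to highlight.
#' @param trim Drop leading/trailing all-zero bins for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.repeat_histogram <- function(object, normalize = TRUE, M = NULL,
                                      trim = TRUE, ...) {
  hist <- as_repeat_histogram(object)
  if (normalize && sum(hist$count) > 0) hist <- normalize_histogram(hist)
  df <- tibble::as_tibble(hist)
  if (trim && any(df$count > 0)) {
    nz <- range(which(df$count > 0))
    df <- df[max(1, nz[1] - 2):min(nrow(df), nz[2] + 2), ]
  }
  df$progenitor <- if (!is.null(M)) df$i == M else FALSE
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$count,
                                        fill = .data$progenitor)) +
    ggplot2::geom_col(width = 0.9, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35",
                                          `TRUE` = "#2166AC")) +
    ggplot2::labs(
      x = "uninterrupted repeat units (i)",
      y = if (normalize) "reads (normalized to 1,000)" else "reads",
      title = attr(hist, "sample_id")) +
    ggplot2::theme_minimal()
  p
}

#' @rdname autoplot.repeat_histogram
#' @export
autoplot.sizing_result <- function(object, ...) {
  autoplot.repeat_histogram(object$histogram, ...)
}

#' Plot the somatic gain distribution of the mutant allele
#'
#' @param hist A `repeat_histogram`.
#' @param M Progenitor repeat count.
#' @return A ggplot object.
#' @export
plot_gain_distribution <- function(hist, M) {
  df <- gain_distribution(hist, M)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gain, y = .data$fraction)) +
    ggplot2::geom_col(width = 0.9, fill = "grey35") +
    ggplot2::labs(x = "CAG tract length increase (RU)",
                  y = "fraction of mutant-range reads") +
    ggplot2::theme_minimal()
}

#' Plot a cohort comparison
#'
#' Per-donor statistic values by cell type with group means, the standard
#' display for MSLG/RoSE comparisons across cell types.
#'
#' @param object A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- object$data
  means <- dplyr::summarise(dplyr::group_by(df, .data$group),
                            value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = means, shape = 95, size = 10,
                        colour = "#B2182B") +
    ggplot2::labs(x = NULL, y = "statistic",
                  subtitle = sprintf("one-way ANOVA: F = %.3g, p = %.3g",
                                     object$anova$F, object$anova$p)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
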