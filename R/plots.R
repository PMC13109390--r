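#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment
#'   geom_vline geom_tile geom_histogram geom_errorbarh facet_grid
#'   facet_wrap labs scale_fill_gradient2 theme_minimal
#' @export
ggplot2::autoplot

#' Plot a breeding-progress summary
#'
#' One row per trait: the p10-p90 box of environment RBPs, the median (open
#' circle), the mean (short vertical tick) and the x = 1 no-change line,
#' coloured by trend class when present.
#'
#' @param object A `progress_summary` tibble (see [summarize_progress()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.progress_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"trend_class" %in% names(df)) df$trend_class <- "unclassified"
  ggplot(df, aes(y = .data$trait)) +
    geom_segment(aes(x = .data$rbp_p10, xend = .data$rbp_p90,
                     yend = .data$trait, colour = .data$trend_class),
                 linewidth = 4, alpha = 0.5) +
    geom_point(aes(x = .data$rbp_median), shape = 1, size = 3) +
    geom_point(aes(x = .data$rbp_mean), shape = 124, size = 4) +
    geom_vline(xintercept = 1, colour = "red") +
    labs(x = "Relative breeding progress (2010 / 1970)", y = NULL,
         colour = "trend") +
    theme_minimal()
}

#' Plot plasticity breeding progress
#'
#' Slope-and-interval plot of the absolute breeding progress of the
#' plasticity index per trait and environment class.
#'
#' @param df Output of [plasticity_progress()].
#' @return A ggplot object.
#' @export
plot_plasticity_progress <- function(df) {
  check_columns(df, c("trait", "env_class", "slope", "ci_lo", "ci_hi"),
                "df")
  ggplot(df, aes(y = interaction(.data$trait, .data$env_class, sep = " / "))) +
    geom_errorbarh(aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                   height = 0.2) +
    geom_point(aes(x = .data$slope), shape = 124, size = 4) +
    geom_vline(xintercept = 0, colour = "red") +
    labs(x = "Breeding progress in plasticity (per year)", y = NULL) +
    theme_minimal()
}

#' Plot a sensitivity map
#'
#' Heatmap of the windowed sensitivity scan: window center on x, weather
#' variable on y, faceted by trait and cultivar group; fill is either the
#' median normalized coefficient (percent per unit) or the median -ln(p).
#'
#' @param object A `sensitivity_map` tibble
#'   (see [group_sensitivity_map()]).
#' @param fill `"sensitivity"` (default) or `"neglogp"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_map <- function(object,
                                     fill = c("sensitivity", "neglogp"),
                                     ...) {
  fill <- match.arg(fill)
  df <- tibble::as_tibble(object)
  if (fill == "sensitivity") {
    p <- ggplot(df, aes(.data$center, .data$variable,
                        fill = .data$median_sensitivity)) +
      scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                           midpoint = 0, name = "sensitivity (%)")
  } else {
    df <- df[df$group != "difference", , drop = FALSE]
    p <- ggplot(df, aes(.data$center, .data$variable,
                        fill = .data$median_neglogp)) +
      ggplot2::scale_fill_viridis_c(name = "-ln(p)")
  }
  p + geom_tile() +
    facet_grid(trait ~ group) +
    labs(x = "Thermal time relative to heading (degC d)", y = NULL) +
    theme_minimal()
}

#' Plot the permutation null of a selection test
#'
#' @param object A `ghat_test` object.
#' @param ... Unused.
#' @return A ggplot object: histogram of permuted statistics with the
#'   observed value marked.
#' @export
autoplot.ghat_test <- function(object, ...) {
  ggplot(tibble::tibble(null = object$null), aes(.data$null)) +
    geom_histogram(bins = 40, fill = "grey70") +
    geom_vline(xintercept = object$ghat, colour = "red") +
    labs(x = "Permuted Ghat statistic", y = "count",
         subtitle = sprintf("observed = %.3g, p = %.3g", object$ghat,
                            object$p_perm)) +
    theme_minimal()
}

#' Plot selection results across traits and environments
#'
#' Tile plot of the effect/frequency-change correlation with significance
#' marks, one cell per trait-environment combination (single-cell tables
#' plot a single tile).
#'
#' @param df Tibble with at least `cor` and `p_perm`; optional `trait` and
#'   `environment` columns define the grid.
#' @param alpha Significance threshold for the marks, default 0.1.
#' @return A ggplot object.
#' @export
plot_selection_results <- function(df, alpha = 0.1) {
  check_columns(df, c("cor", "p_perm"), "df")
  if (!"trait" %in% names(df)) df$trait <- "trait"
  if (!"environment" %in% names(df)) df$environment <- "pooled"
  df$mark <- ifelse(df$p_perm < alpha, "*", "")
  ggplot(df, aes(.data$environment, .data$trait, fill = .data$cor)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = .data$mark), size = 8) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = 0, limits = c(-1, 1), name = "cor") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
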