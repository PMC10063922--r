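# ggplot2 views of the result tables: per-population frequency strip plots
# (the layout of the per-tissue frequency figures), subset-distribution
# charts (pie-style composition), and concordance-pattern panels.

#' Per-population CLL-SLS frequency strip plot
#'
#' One point per donor, per population, on the percent scale.
#'
#' @param summary A [summarize_populations()] result.
#' @param tier `"standard"` or `"satellite"`.
#' @return A ggplot object.
#' @export
plot_population_frequencies <- function(summary, tier = c("standard", "satellite")) {
  tier <- match.arg(tier)
  col <- paste0("freq_", tier)
  ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$population, y = 100 * .data[[col]])
  ) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(
      fun = stats::median, geom = "crossbar",
      width = 0.5, linewidth = 0.3, colour = "grey30"
    ) +
    ggplot2::labs(
      x = NULL, y = sprintf("%s CLL-SLS frequency (%% of unique sequences)", tier)
    ) +
    ggplot2::theme_classic()
}

#' @export
autoplot.sls_population_summary <- function(object, tier = "standard", ...) {
  plot_population_frequencies(object, tier = tier)
}

#' Subset composition of the matched CLL-SLS
#'
#' Stacked composition bar (a pie chart unrolled) of the matched clonotypes
#' per subset; set `polar = TRUE` for the classic pie.
#'
#' @param distribution A [subset_distribution()] result (pooled form).
#' @param polar Draw as a pie chart.
#' @return A ggplot object.
#' @export
plot_subset_distribution <- function(distribution, polar = FALSE) {
  p <- ggplot2::ggplot(
    distribution,
    ggplot2::aes(x = "", y = .data$fraction, fill = .data$subset_id)
  ) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::labs(x = NULL, y = "fraction of matched CLL-SLS", fill = "subset") +
    ggplot2::theme_minimal()
  if (polar) p <- p + ggplot2::coord_polar(theta = "y")
  p
}

#' Concordance-pattern panels
#'
#' Mutation-status concordance of each subset across populations, coloured
#' and facetted by pattern group.
#'
#' @param patterns A [group_patterns()] result.
#' @return A ggplot object.
#' @export
plot_concordance_patterns <- function(patterns) {
  ggplot2::ggplot(
    patterns,
    ggplot2::aes(
      x = .data$population, y = .data$concordance,
      group = .data$subset_id, colour = .data$subset_id
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~pattern_id) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "fraction matching the subset's canonical IGHV status",
      colour = "subset"
    ) +
    ggplot2::theme_bw()
}

#' @export
autoplot.sls_patterns <- function(object, ...) {
  plot_concordance_patterns(object)
}
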