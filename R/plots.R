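# ggplot2 displays for the main result types.

#' Ordination plot of an NMDS solution
#'
#' @param object A `fwd_nmds` object.
#' @param metadata Optional sample metadata; when given, points are
#'   coloured by tree species and shaped by canopy.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fwd_nmds <- function(object, metadata = NULL, ...) {
  df <- tidy(object)
  p <- if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
    ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2,
                                     colour = .data$tree,
                                     shape = .data$canopy))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  }
  p + ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      caption = sprintf("Kruskal stress-1 = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Specificity versus succession time display
#'
#' Scatter of per-taxon succession time against specificity with the
#' specialist thresholds (0.95 / 0.05) marked.
#'
#' @param records Tibble from [succession_table()].
#' @param factor `"tree"` or `"canopy"`.
#' @return A ggplot object.
#' @export
plot_specificity <- function(records, factor = c("tree", "canopy")) {
  factor <- match.arg(factor)
  col <- if (factor == "tree") "s_tree" else "s_canopy"
  df <- records[!is.na(records[[col]]) & !is.na(records$succession_time), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$succession_time, .data[[col]])) +
    ggplot2::geom_hline(yintercept = c(0.05, 0.95),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "succession time (years)",
                  y = paste(factor, "specificity")) +
    ggplot2::theme_minimal()
}

#' Guild composition over time
#'
#' Stacked area/bar chart of guild shares per group from [guild_profile()].
#'
#' @param profile Tibble from [guild_profile()] grouped by (at least) year.
#' @return A ggplot object.
#' @export
plot_guild_profile <- function(profile) {
  facets <- setdiff(names(profile), c("year", "guild", "share"))
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(.data$year, .data$share,
                                    fill = .data$guild)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "year of decomposition", y = "share of community") +
    ggplot2::theme_minimal()
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_wrap(facets)
  }
  p
}

#' Chemistry trajectories
#'
#' Mean per-year trajectories of the wood-chemistry covariates by tree
#' species.
#'
#' @param chemistry Tibble from [generate_chemistry()].
#' @param metadata Sample metadata tibble.
#' @return A ggplot object.
#' @export
plot_chemistry <- function(chemistry, metadata) {
  df <- dplyr::left_join(chemistry, metadata, by = "sample_id") |>
    tidyr::pivot_longer(dplyr::all_of(c("pH", "ergosterol", "C", "N",
                                        "moisture")),
                        names_to = "variable", values_to = "value") |>
    dplyr::group_by(.data$tree, .data$year, .data$variable) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$value,
                                   colour = .data$tree)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap("variable", scales = "free_y") +
    ggplot2::labs(x = "year of decomposition", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
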