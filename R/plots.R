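#' Plot the exclusivity distribution
#'
#' Histogram of E scores with the two percentile cutoffs, coloured by level.
#'
#' @param object A `semdim_exclusivity` from [assign_levels()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.semdim_exclusivity <- function(object, bins = 40, ...) {
  cuts <- level_cutoffs(object)
  ggplot(as_tibble(object), aes(x = .data$E, fill = .data$level)) +
    geom_histogram(bins = bins, colour = "grey30", linewidth = 0.2) +
    geom_vline(xintercept = c(cuts$p25, cuts$p75), linetype = "dashed") +
    scale_fill_manual(values = c(low = "#4477AA", medium = "#66BB77",
                                 high = "#CC6677")) +
    labs(x = "Exclusivity E", y = "Words", fill = "Level",
         title = "Exclusivity distribution",
         subtitle = sprintf("cutoffs: %.2f / %.2f (%s percentiles)",
                            cuts$p25, cuts$p75, cuts$method)) +
    theme_minimal()
}

#' UpSet-style plot of dimension intersections
#'
#' Bar chart of exact-combination word counts (top `n_max` combinations) with
#' a membership dot matrix underneath, the tabular core of an UpSet plot.
#'
#' @param object A `semdim_intersections` from [intersection_table()].
#' @param n_max Number of combinations to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.semdim_intersections <- function(object, n_max = 20, ...) {
  tab <- head(as_tibble(object), n_max) |>
    mutate(rank = dplyr::row_number())
  dims <- rev(semantic_dimensions())
  dots <- tab |>
    tidyr::unnest_longer("dims", values_to = "dimension") |>
    mutate(dimension = factor(.data$dimension, levels = dims))
  scale_y <- max(tab$n)
  dot_y <- -scale_y * (0.08 + 0.05 * (seq_along(dims) - 1))
  names(dot_y) <- dims
  ggplot(tab, aes(x = .data$rank)) +
    geom_col(aes(y = .data$n), fill = "#4477AA") +
    geom_point(
      data = dots,
      aes(y = dot_y[as.character(.data$dimension)]),
      size = 2
    ) +
    geom_line(
      data = dots,
      aes(y = dot_y[as.character(.data$dimension)], group = .data$rank),
      linewidth = 0.4
    ) +
    scale_y_continuous(
      breaks = pretty(c(0, scale_y)),
      minor_breaks = NULL
    ) +
    annotate("text", x = 0.2, y = dot_y, label = dims, hjust = 1, size = 2.8) +
    coord_cartesian(xlim = c(-1.5, nrow(tab) + 0.5)) +
    labs(x = "Dimension combination", y = "Words",
         title = "Exact dimension-combination counts") +
    theme_minimal() +
    theme(axis.text.x = element_blank())
}

#' Heatmap of the dimension co-occurrence network
#'
#' Jaccard similarity between dimensions, ordered by the 2-cluster partition.
#'
#' @param object A `semdim_conetwork` from [cooccurrence()].
#' @param k Number of clusters used for ordering.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.semdim_conetwork <- function(object, k = 2, ...) {
  cl <- cluster_dimensions(object, k = k)
  ord <- cl$dimension[order(cl$cluster)]
  df <- as_tibble(as.table(object$jaccard), .name_repair = "minimal")
  names(df) <- c("dim_a", "dim_b", "jaccard")
  df$dim_a <- factor(df$dim_a, levels = ord)
  df$dim_b <- factor(df$dim_b, levels = ord)
  ggplot(df, aes(.data$dim_a, .data$dim_b, fill = .data$jaccard)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#4477AA", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Jaccard",
         title = "Dimension co-occurrence (ordered by cluster)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
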