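#' Plot a mismatch spectrum with an optional fitted expectation
#'
#' @param object A [mismatch_spectrum()].
#' @param fit Optional [fit_expansion()] result; when supplied the
#'   Rogers-Harpending expectation is overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mismatch_spectrum
#' @export
autoplot.mismatch_spectrum <- function(object, fit = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$differences,
                                        y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30", width = 0.9) +
    ggplot2::labs(x = "Pairwise differences", y = "Relative frequency") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    jmax <- length(object$counts) - 1
    exp_df <- tibble(
      differences = 0:jmax,
      frequency = model_spectrum(jmax, fit$tau, fit$theta0, fit$theta1)
    )
    p <- p + ggplot2::geom_line(data = exp_df, colour = "firebrick",
                                linewidth = 0.8) +
      ggplot2::geom_point(data = exp_df, colour = "firebrick", size = 1.2)
  }
  p
}

#' Plot an MDS embedding of populations
#'
#' @param object An [classical_mds()] embedding.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mds_embedding
#' @export
autoplot.mds_embedding <- function(object, ...) {
  df <- object$coordinates
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                   label = .data$population)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = "Dimension 1", y = "Dimension 2",
      caption = paste0("stress = ", signif(object$stress, 3))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a median-joining haplotype network
#'
#' Fruchterman-Reingold layout via igraph; node size scales with the
#' total sample count, medians drawn as open squares.
#'
#' @param object A [median_joining()] network.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot haplotype_network
#' @export
autoplot.haplotype_network <- function(object, seed = 1, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes$id)
  xy <- with_seed_(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  count_cols <- setdiff(names(nodes), c("id", "type"))
  nodes$total <- if (length(count_cols)) {
    rowSums(as.matrix(nodes[, count_cols, drop = FALSE]))
  } else 1
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  edge_df <- object$edges |>
    left_join(nodes |> select("id", "x", "y"), by = c("from" = "id")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nodes |> select("id", "x", "y"), by = c("to" = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edge_df,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x, yend = .data$y),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   size = .data$total, shape = .data$type),
      fill = "steelblue", colour = "grey20"
    ) +
    ggplot2::scale_shape_manual(values = c(observed = 21, median = 22)) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::theme_void()
}

#' Stacked-bar plot of haplogroup frequencies per population
#'
#' @param freqs A [haplogroup_frequencies()] table.
#' @return A ggplot.
#' @export
plot_haplogroup_frequencies <- function(freqs) {
  ggplot2::ggplot(freqs, ggplot2::aes(x = .data$population,
                                      y = .data$freq,
                                      fill = .data$haplogroup)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Frequency", fill = "Haplogroup") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
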