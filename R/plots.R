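#' Posterior density of the dyadic persistence coefficient
#'
#' @param object An `ame_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ame_fit <- function(object, ...) {
  dr <- tidyr::pivot_longer(object$draws, cols = c("beta0", "beta_dyad"),
                            names_to = "term", values_to = "draw")
  ggplot2::ggplot(dr, ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "posterior draw", y = "density",
                  title = "Network probit regression: posterior distributions") +
    ggplot2::theme_minimal()
}

#' Dyad-state transition heatmap
#'
#' @param object A `transition_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transition_table <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$period2, y = .data$period1,
                               fill = .data$n_dyads)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_dyads), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "state in later period", y = "state in earlier period",
                  title = "Dyad co-breeding states across periods") +
    ggplot2::theme_minimal()
}

#' Plot an association network from an edge list
#'
#' Lays the network out with a force-directed algorithm and draws edges
#' weighted by association strength -- the conventional display for
#' comparing cohesion between study phases.
#'
#' @param edges Edge tibble from [export_edges()].
#' @param individuals Optional full node set so isolates are drawn.
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_network <- function(edges, individuals = NULL, seed = 1L) {
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                     vertices = individuals)
  withr::local_seed(seed)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = lay[, 1L], y = lay[, 2L])
  seg <- edges %>%
    dplyr::left_join(nodes, by = c(source = "name")) %>%
    rename(x0 = "x", y0 = "y") %>%
    dplyr::left_join(nodes, by = c(target = "name")) %>%
    rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       linewidth = .data$weight),
                          colour = "grey55", alpha = 0.6) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2, colour = "steelblue") +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Co-breeding association network")
}
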