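#' Plot a bin clustering in the BAF-RDR plane
#'
#' One panel per sample; each point is a genomic bin placed at its
#' (mirrored BAF, RDR) coordinates and colored by cluster, with cluster
#' centroids overplotted.
#'
#' @param object A `bin_clustering`.
#' @param signals The per-bin signal tibble the clustering was built from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bin_clustering <- function(object, signals, ...) {
  df <- dplyr::inner_join(signals, object$assignment, by = "bin")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$baf, y = .data$rdr,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_point(data = object$clusters, shape = 4, size = 3,
                        stroke = 1.2) +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "mirrored BAF", y = "RDR", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot the copy-number states and proportions of a solution
#'
#' Tile plot of allele-specific states (cluster x clone), annotated with
#' the clone proportions per sample.
#'
#' @param object A `cna_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cna_solution <- function(object, ...) {
  df <- tidy(object)
  df$state <- paste0(df$a, "|", df$b)
  df$total <- df$a + df$b
  ggplot2::ggplot(dplyr::distinct(df, .data$cluster, .data$clone,
                                  .data$state, .data$total),
                  ggplot2::aes(x = .data$clone, y = .data$cluster,
                               fill = .data$total)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$state), size = 3) +
    ggplot2::scale_fill_gradient2(midpoint = 2, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = "cluster", fill = "total CN") +
    ggplot2::theme_minimal()
}

#' Per-sample clone-proportion bar plot
#'
#' @param solution A `cna_solution`.
#' @return A ggplot object.
#' @export
plot_clone_proportions <- function(solution) {
  U <- solution$U
  df <- tibble::as_tibble(as.data.frame.table(U, responseName = "proportion"))
  names(df)[1:2] <- c("clone", "sample")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$proportion,
                                   fill = .data$clone)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "clone proportion") +
    ggplot2::theme_minimal()
}
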