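#' Force-directed layout of a pruned union graph
#'
#' Embeds the reference nodes in 2-D by spring-energy minimization
#' (Kamada-Kawai, with the per-edge mean distances as target spring
#' lengths), starting from a deterministic circular placement so the
#' layout is reproducible. When a `reference_node_set` is supplied, each
#' retained cell inherits its node's position plus a small seeded
#' Gaussian jitter (SD = 2% of the layout diameter) to avoid
#' overplotting.
#'
#' @param graph a connected (typically pruned) [union_graph()].
#' @param nodes optional `reference_node_set` for per-cell coordinates.
#' @param seed RNG seed for the cell jitter.
#' @return A `layout_result`: list with `node_coords` (k x 2), `edges`
#'   (the graph's edge list), and, when `nodes` is given, `cell_coords`
#'   (rows = cells, `NA` for outliers).
#' @export
force_layout <- function(graph, nodes = NULL, seed = 1) {
  k <- attr(graph, "k")
  g <- igraph::graph_from_data_frame(graph[, c("i", "j")], directed = FALSE,
                                     vertices = data.frame(name = seq_len(k)))
  coords <- igraph::layout_with_kk(g, weights = graph$mean_distance,
                                   coords = igraph::layout_in_circle(g))
  # KK output is scale-normalized; rescale so realized edge lengths match
  # the spring targets in the least-squares (stress-optimal) sense
  d_e <- sqrt(rowSums((coords[graph$i, , drop = FALSE] -
                         coords[graph$j, , drop = FALSE])^2))
  if (sum(d_e^2) > 0)
    coords <- coords * sum(d_e * graph$mean_distance) / sum(d_e^2)
  colnames(coords) <- c("x", "y")
  out <- list(node_coords = coords, edges = graph)
  if (!is.null(nodes)) {
    diam <- max(dist(coords))
    cc <- matrix(NA_real_, length(nodes$assignment), 2)
    ret <- nodes$retained
    base <- coords[nodes$assignment[ret], , drop = FALSE]
    jit <- .with_seed(seed,
                      matrix(rnorm(2 * length(ret), sd = 0.02 * diam),
                             ncol = 2))
    cc[ret, ] <- base + jit
    colnames(cc) <- c("x", "y")
    out$cell_coords <- cc
  }
  structure(out, class = "layout_result")
}

#' Plot a layout with marker or branch overlays
#'
#' Scatter of cell positions coloured by a continuous marker value or by
#' branch labels; branch-point cells are drawn black. The figure is
#' written to `file` (format by extension: pdf, png or svg).
#'
#' @param layout a `layout_result` with cell coordinates.
#' @param values numeric per-cell values (e.g. one species' abundance),
#'   or `NULL`.
#' @param labels character per-cell labels (e.g. `cell_branches`), or
#'   `NULL`.
#' @param file output path.
#' @param title optional plot title.
#' @return Invisibly, the path written.
#' @export
overlay_plot <- function(layout, values = NULL, labels = NULL, file,
                         title = NULL) {
  cc <- layout$cell_coords
  if (is.null(cc)) stop("layout has no cell coordinates; pass nodes to force_layout()")
  ok <- !is.na(cc[, 1])
  df <- data.frame(x = cc[ok, 1], y = cc[ok, 2])
  if (!is.null(values)) {
    if (length(values) != nrow(cc)) stop("values length does not match cells")
    df$value <- values[ok]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                          colour = value)) +
      ggplot2::geom_point(size = 0.4) +
      ggplot2::scale_colour_viridis_c()
  } else if (!is.null(labels)) {
    if (length(labels) != nrow(cc)) stop("labels length does not match cells")
    df$branch <- labels[ok]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                          colour = branch)) +
      ggplot2::geom_point(size = 0.4) +
      ggplot2::scale_colour_discrete(na.value = "grey80")
    if (any(df$branch == "branch point", na.rm = TRUE))
      p <- p + ggplot2::geom_point(
        data = df[!is.na(df$branch) & df$branch == "branch point", ],
        colour = "black", size = 0.6)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
      ggplot2::geom_point(size = 0.4)
  }
  p <- p + ggplot2::theme_minimal() + ggplot2::coord_equal()
  if (!is.null(title)) p <- p + ggplot2::ggtitle(title)
  ggplot2::ggsave(file, p, width = 6, height = 5)
  invisible(file)
}
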