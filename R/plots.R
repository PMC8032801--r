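# Minimal rectangular tree layout (no ggtree dependency): x = root-path
# length (unit branches when lengths are absent), y = tip order.
tree_layout <- function(tree) {
  ntip <- length(tree$tip.label)
  work <- tree
  if (is.null(work$edge.length)) work$edge.length <- rep(1, nrow(work$edge))
  x <- ape::node.depth.edgelength(work)
  y <- numeric(ntip + tree$Nnode)
  y[seq_len(ntip)] <- seq_len(ntip)
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]
    kids <- tree$edge[tree$edge[, 1] == p, 2]
    y[p] <- mean(y[kids])
  }
  list(x = x, y = y, edge = tree$edge, ntip = ntip)
}

#' Plot a Dollo reconstruction
#'
#' Draws the species tree with presence states: edges carrying the family
#' are solid, loss edges are highlighted, and the gain node is marked.
#'
#' @param object A `dollo_recon`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dollo_recon
#' @export
autoplot.dollo_recon <- function(object, ...) {
  lay <- tree_layout(object$tree)
  states <- unname(object$states)
  loss_children <- object$losses$child
  seg <- tibble(
    x = lay$x[lay$edge[, 1]], xend = lay$x[lay$edge[, 2]],
    y = lay$y[lay$edge[, 2]], yend = lay$y[lay$edge[, 2]],
    status = dplyr::case_when(
      lay$edge[, 2] %in% loss_children ~ "loss",
      states[lay$edge[, 1]] == 1 & states[lay$edge[, 2]] == 1 ~ "present",
      TRUE ~ "absent"
    )
  )
  vert <- tibble(
    x = lay$x[lay$edge[, 1]], xend = lay$x[lay$edge[, 1]],
    y = lay$y[lay$edge[, 1]], yend = lay$y[lay$edge[, 2]],
    status = "backbone"
  )
  tips <- tibble(x = lay$x[seq_len(lay$ntip)], y = lay$y[seq_len(lay$ntip)],
                 label = object$tree$tip.label,
                 present = states[seq_len(lay$ntip)] == 1)
  gain <- tibble(x = lay$x[object$gain_node], y = lay$y[object$gain_node])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = vert,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend),
      colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend,
                   colour = .data$status),
      linewidth = 0.5
    ) +
    ggplot2::geom_point(data = gain, ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 23, size = 3, fill = "gold") +
    ggplot2::geom_text(
      data = tips,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                   colour = ifelse(.data$present, "present", "absent")),
      hjust = -0.1, size = 2.5, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(
      present = "steelblue4", absent = "grey70", loss = "firebrick",
      backbone = "grey60"
    )) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.15))) +
    ggplot2::labs(
      title = sprintf("%s: gain at %s, %d independent losses",
                      object$family, object$gain_label, object$min_losses),
      x = NULL, y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot a repertoire report as a count heatmap
#'
#' @param object A `repertoire_report`.
#' @param ... Unused.
#' @return A ggplot object (species by family, tile fill = gene count).
#' @method autoplot repertoire_report
#' @export
autoplot.repertoire_report <- function(object, ...) {
  ggplot2::ggplot(object$counts_long,
                  ggplot2::aes(x = .data$family, y = .data$species,
                               fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey95", high = "steelblue4",
                                 trans = "sqrt") +
    ggplot2::labs(x = NULL, y = NULL, fill = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}
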