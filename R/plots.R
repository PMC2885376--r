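#' Plot a co-inertia result
#'
#' The linked two-panel display: sample (or group) points of table X on the
#' left, miRNA points on the right, both on co-inertia axes 1-2 (or axis 1
#' against rank when only one axis exists). Reading rule: a miRNA lying
#' opposite a sample group through the origin is inferred active in that
#' group. Requires the patchwork package for the side-by-side layout;
#' without it the two panels are returned as a list.
#'
#' @param object A `"coinertia"` object.
#' @param groups Optional data frame (`sample_id`, `group`) to colour the
#'   sample panel.
#' @param ... Unused.
#' @return A patchwork object (or list of two ggplots).
#' @export
autoplot.coinertia <- function(object, groups = NULL, ...) {
  sx <- panel_data(object$display_X, "id")
  sy <- panel_data(object$display_Y, "id")
  if (!is.null(groups)) {
    groups <- as_tibble(groups)
    sx$group <- groups$group[match(sx$id, groups$sample_id)]
  }
  p1 <- panel_plot(sx, colour = !is.null(groups)) +
    ggplot2::ggtitle("Samples")
  p2 <- panel_plot(sy, colour = FALSE) + ggplot2::ggtitle("miRNAs")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p1 + p2
  } else {
    list(samples = p1, mirnas = p2)
  }
}

# coordinates for one scatter panel; single-axis results plot axis1 vs rank
panel_data <- function(m, id_name) {
  if (ncol(m) >= 2) {
    tibble(id = rownames(m), x = m[, 1], y = m[, 2])
  } else {
    tibble(id = rownames(m), x = m[, 1], y = rank(m[, 1]))
  }
}

panel_plot <- function(d, colour) {
  mapping <- if (colour) {
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y)
  }
  ggplot2::ggplot(d, mapping) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Axis 1", y = "Axis 2") +
    ggplot2::theme_minimal()
}

#' Plot a supervised miRNA axis
#'
#' Dot plot of the single ranked miRNA axis: coordinate against rank, most
#' negative (inferred active in the target group) at the top, the top `n`
#' labelled.
#'
#' @param object A `"supervised_cia"` object.
#' @param n_label Number of top miRNAs to label.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.supervised_cia <- function(object, n_label = 10, ...) {
  rl <- as_tibble(rank_mirnas(object))
  rl$label <- ifelse(rl$rank <= n_label, rl$mirna_id, "")
  ggplot2::ggplot(rl, ggplot2::aes(x = .data$coordinate,
                                   y = -.data$rank)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.15,
                       size = 3) +
    ggplot2::labs(
      x = sprintf("Axis 1 (target group '%s' positive)", object$target_group),
      y = "miRNA (ranked)",
      title = sprintf("miRNAs inferred active in '%s' (%s)",
                      object$target_group, object$source_label)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
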