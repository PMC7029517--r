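#' @method autoplot dmn_scan
#' @export
autoplot.dmn_scan <- function(object, alpha = 0.05, ...) {
  res <- dplyr::filter(object$results, !is.na(.data$p.value))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$block, y = -log10(.data$p.value))) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$bh_rejected),
                         width = 0.15, height = 0) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(
      x = "subsystem block", y = expression(-log[10](p)),
      colour = "BH rejected",
      title = sprintf("Node-pair scan: %s", object$term)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @method autoplot dmn_enrichment
#' @export
autoplot.dmn_enrichment <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pool, y = .data$proportion)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$binomial_expectation),
                        shape = 4, size = 3) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("share of matrices with >= %d significant entries",
                  object$min_significant),
      title = sprintf("Enrichment bootstrap: chi-squared = %.1f, p = %.2g",
                      object$statistic, object$p.value),
      caption = "crosses: closed-form binomial expectation at the pool's significant fraction"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of one subject's connectivity vector
#'
#' @param connectivity named connectivity vector (pair keys) or a one-row
#'   connectivity tibble.
#' @param map subsystem map.
#' @return a ggplot object.
#' @export
plot_connectivity_matrix <- function(connectivity, map = dmn_nodes()) {
  if (is.data.frame(connectivity)) {
    stopifnot(nrow(connectivity) == 1L)
    keys <- dmn_node_pairs(map)$pair
    connectivity <- unlist(connectivity[, keys])
  }
  pairs <- dmn_node_pairs(map)
  abbr <- map$abbreviation[order(map$node_id)]
  d <- tibble::tibble(
    row = factor(abbr[pairs$a + 1L], levels = abbr),
    col = factor(abbr[pairs$b + 1L], levels = abbr),
    r = unname(connectivity[pairs$pair])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}
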