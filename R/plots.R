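#' @export
autoplot.screen_result <- function(object, ...) {
  df <- tidy(object)
  df$feature <- ifelse(is.na(df$gene_q), df$gene_p,
                       paste0(df$gene_p, "|", df$gene_q))
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$t_score), y = .data$feature)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$feature),
                          linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "|t|", y = NULL,
      title = sprintf("Top %d features (%s screen)",
                      attr(object, "top_n"), attr(object, "method"))
    )
}

#' @export
autoplot.sim_study_result <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$k, .data$classifier, .data$scheme) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$accuracy,
                                   colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$classifier)) +
    ggplot2::scale_x_continuous(breaks = unique(df$k)) +
    ggplot2::labs(x = "number of abs-pairs (k)",
                  y = "mean 5-fold CV accuracy (%)", colour = NULL)
}

#' Rank-space scatterplot of a gene pair
#'
#' The diagnostic view of a candidate synergic pair: each sample plotted
#' at its two gene ranks, coloured by class. A genuine abs-type synergy
#' shows one class hugging the diagonal and the other in the off-diagonal
#' wedges.
#'
#' @param ranks A `rank_matrix` (or `expr_dataset`, ranked on the fly).
#' @param p,q Gene ids or indices.
#' @return A ggplot object.
#' @export
plot_pair <- function(ranks, p, q) {
  if (inherits(ranks, "expr_dataset")) ranks <- rank_transform(ranks)
  stopifnot(inherits(ranks, "rank_matrix"))
  pi <- resolve_gene(ranks, p)
  qi <- resolve_gene(ranks, q)
  df <- tibble::tibble(
    rp = ranks$ranks[pi, ],
    rq = ranks$ranks[qi, ],
    class = factor(unname(ranks$labels))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rp, y = .data$rq,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("rank of %s", rownames(ranks$ranks)[pi]),
                  y = sprintf("rank of %s", rownames(ranks$ranks)[qi]),
                  colour = "class")
}

#' Heat map of converted pair features
#'
#' Converts the pairs of a screen result under one conversion type,
#' rescales each feature row to \[-1, 1\] with [heatmap_values()], and
#' tiles features by samples with samples grouped by class — the visual
#' check that a conversion type separates the classes.
#'
#' @param ranks A `rank_matrix` (or `expr_dataset`).
#' @param result A `screen_result` of pairs.
#' @param conversion Conversion used for display; defaults to the one in
#'   `result`.
#' @return A ggplot object.
#' @export
plot_conversion_heatmap <- function(ranks, result, conversion = NULL) {
  if (inherits(ranks, "expr_dataset")) ranks <- rank_transform(ranks)
  z <- t(pair_features(ranks, result, conversion))
  h <- heatmap_values(z)
  ord <- order(ranks$labels)
  df <- tibble::tibble(
    pair = rep(rownames(h), times = ncol(h)),
    sample = rep(factor(colnames(h)[ord], levels = colnames(h)[ord]),
                 each = nrow(h)),
    value = as.vector(h[, ord])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$pair,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "samples (grouped by class)", y = NULL,
                  fill = "scaled Z")
}
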