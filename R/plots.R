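# ggplot2 views of the pipeline's result objects.

#' @export
autoplot.pca_result <- function(object, colour = NULL, shape = NULL,
                                components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  p <- ggplot2::ggplot(
    object$scores,
    ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])
  )
  p <- if (!is.null(colour) && !is.null(shape)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]],
                                         shape = .data[[shape]]), size = 2)
  } else if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("%s (%.0f%%)", pcs[1],
                  100 * object$variance_ratio[components[1]]),
      y = sprintf("%s (%.0f%%)", pcs[2],
                  100 * object$variance_ratio[components[2]])
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_set <- function(object, clusters = NULL, ...) {
  ids <- clusters %||% seq_len(min(object$k, 12L))
  df <- tibble::as_tibble(object$centroids[ids, , drop = FALSE],
                          rownames = NULL)
  df$cluster <- factor(ids)
  long <- tidyr::pivot_longer(df, -"cluster", names_to = "condition",
                              values_to = "profile")
  long$condition <- factor(long$condition,
                           levels = colnames(object$centroids))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$profile,
                                     group = .data$cluster)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "standardized profile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.vim_table <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(dplyr::starts_with("vim_"), names_to = "variable",
                        values_to = "vim", names_prefix = "vim_")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$cluster,
                                                        -.data$vim),
                                     y = .data$vim)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "cluster (ranked)", y = "median VIM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.topk_intersection <- function(object, ...) {
  df <- object$categories
  df$category <- stats::reorder(df$category, -df$n_clusters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = .data$n_clusters)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "top-set membership", y = "clusters") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.set_intersections <- function(object, ...) {
  df <- object$counts
  df$category <- stats::reorder(df$category, -df$n_genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "set membership", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  }

#' Dot plot of term enrichment results
#'
#' @param enrichment Tibble from [hypergeom_enrich()].
#' @param max_terms Terms shown (best first).
#' @export
plot_enrichment <- function(enrichment, max_terms = 15) {
  df <- head(dplyr::arrange(enrichment, .data$p_value), max_terms)
  df$term <- stats::reorder(df$term, df$fold_enrichment)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment, y = .data$term,
                                   size = .data$overlap,
                                   colour = -log10(.data$fdr))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "genes",
                  colour = "-log10 FDR") +
    ggplot2::theme_minimal()
}
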