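#' Heatmap of an item similarity (or correlation) matrix
#'
#' Items are ordered canonically so within-scale blocks appear along the
#' diagonal; scale boundaries are drawn when an item set is supplied.
#'
#' @param S Symmetric matrix with item-id dimnames.
#' @param items Optional `sembed_items` tibble for scale boundary lines.
#' @return A ggplot object.
#' @export
plot_similarity_matrix <- function(S, items = NULL) {
  check_square(S, "similarity matrix")
  ids <- rownames(S)
  df <- tibble::as_tibble(S, .name_repair = "minimal")
  names(df) <- ids
  df$row <- factor(ids, levels = ids)
  long <- tidyr::pivot_longer(df, -"row", names_to = "col", values_to = "value")
  long$col <- factor(long$col, levels = ids)
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                           fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", limits = c(-1, 1),
                                  name = "similarity") +
    ggplot2::scale_y_discrete(limits = rev(ids)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(items)) {
    bounds <- cumsum(table(factor(items$scale_id, levels = scales(items))))
    bounds <- bounds[-length(bounds)] + 0.5
    gg <- gg +
      ggplot2::geom_vline(xintercept = bounds, linewidth = 0.2) +
      ggplot2::geom_hline(yintercept = length(ids) - bounds + 1, linewidth = 0.2)
  }
  gg
}

#' @describeIn plot_similarity_matrix Autoplot for pseudo-similarity objects.
#' @param object A `sembed_pseudo_sim`.
#' @param ... Unused.
#' @export
autoplot.sembed_pseudo_sim <- function(object, ...) {
  plot_similarity_matrix(object$matrix)
}

#' Dot plot of screening fit indices against their cutoffs
#'
#' @param object A `sembed_screen` tibble.
#' @param cutoffs Cutoffs to draw as reference lines.
#' @param ... Unused.
#' @return A ggplot object: one panel per index, models on the y axis,
#'   misfits highlighted.
#' @export
autoplot.sembed_screen <- function(object,
                                   cutoffs = c(incremental = 0.90, absolute = 0.08),
                                   ...) {
  label <- if ("scale_id" %in% names(object)) {
    object$scale_id
  } else {
    paste(object$scale_a, "+", object$scale_b)
  }
  df <- tibble::tibble(
    model = factor(label, levels = rev(unique(label))),
    verdict = object$verdict,
    cfi = object$cfi, tli = object$tli, srmr = object$srmr, rmsea = object$rmsea
  )
  long <- tidyr::pivot_longer(df, c("cfi", "tli", "srmr", "rmsea"),
                              names_to = "index", values_to = "value")
  long$index <- factor(long$index, levels = c("cfi", "tli", "srmr", "rmsea"))
  cuts <- tibble::tibble(
    index = factor(c("cfi", "tli", "srmr", "rmsea"),
                   levels = c("cfi", "tli", "srmr", "rmsea")),
    cut = c(cutoffs[["incremental"]], cutoffs[["incremental"]],
            cutoffs[["absolute"]], cutoffs[["absolute"]])
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$model,
                                     colour = .data$verdict)) +
    ggplot2::geom_point(size = 1.5, na.rm = TRUE) +
    ggplot2::geom_vline(data = cuts, ggplot2::aes(xintercept = .data$cut),
                        linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~index, nrow = 1, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(adequate = "#1b7837", misfit = "#b2182b")) +
    ggplot2::labs(x = "index value", y = NULL, colour = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Scatter of two matrices' lower triangles
#'
#' Visual companion to [lower_triangle_correlation()]: each point is one
#' item pair, similarity-derived value against empirical value.
#'
#' @param A,B Symmetric matrices over the same items.
#' @return A ggplot object with the fitted agreement in the subtitle.
#' @export
plot_matrix_agreement <- function(A, B) {
  agr <- lower_triangle_correlation(A, B)
  df <- tibble::tibble(a = lower_tri_values(A),
                       b = lower_tri_values(B[rownames(A), rownames(A)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "matrix A (lower triangle)", y = "matrix B (lower triangle)",
                  subtitle = sprintf("r = %.3f over %d pairs", agr$r, agr$n_pairs)) +
    ggplot2::theme_minimal(base_size = 9)
}
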