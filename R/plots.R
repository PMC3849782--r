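#' Silhouette plot
#'
#' Horizontal bar plot of per-object silhouette widths, grouped by cluster
#' and sorted within each cluster, with per-cluster mean lines.
#'
#' @param object A `silhouette_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.silhouette_report <- function(object, ...) {
  df <- dplyr::mutate(
    dplyr::arrange(as_tibble(object), .data$cluster, dplyr::desc(.data$s)),
    pos = dplyr::row_number(),
    cluster = factor(.data$cluster)
  )
  means <- dplyr::summarise(
    dplyr::group_by(df, .data$cluster),
    mean_s = mean(.data$s), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$s,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(
      data = means,
      ggplot2::aes(yintercept = .data$mean_s, colour = .data$cluster),
      linetype = "dashed", show.legend = FALSE
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "silhouette width s_i", fill = "cluster",
      title = sprintf("Mean silhouette %.3f", mean(object$s))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Parameter-sweep plot
#'
#' Mean silhouette as a function of the membership exponent r, one line
#' per cluster count k, with the selected cell highlighted.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- dplyr::mutate(object$table, k = factor(.data$k))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r,
                                        y = .data$mean_silhouette,
                                        colour = .data$k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "membership exponent r", y = "mean silhouette", colour = "k"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$selected)) {
    p <- p + ggplot2::annotate(
      "point",
      x = object$selected$r, y = object$selected$mean_silhouette,
      shape = 1, size = 4, colour = "black"
    )
  }
  p
}

#' Membership heatmap
#'
#' Tile plot of the fuzzy membership matrix, objects ordered by hard
#' cluster then membership strength.
#'
#' @param fit A `fanny_fit`.
#' @return A ggplot object.
#' @export
plot_membership <- function(fit) {
  stopifnot(inherits(fit, "fanny_fit"))
  ord <- dplyr::arrange(fit$hard_labels, .data$cluster,
                        dplyr::desc(.data$membership))
  df <- dplyr::mutate(
    tidy(fit),
    id = factor(.data$id, levels = ord$id),
    cluster = factor(.data$cluster)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$id,
                                   fill = .data$membership)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "cluster", y = NULL, fill = "u") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
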