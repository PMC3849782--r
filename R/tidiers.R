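#' Tidy a fanny fit into a long membership tibble
#'
#' @param x A `fanny_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (object, cluster): `id`, `cluster`,
#'   `membership`.
#' @export
tidy.fanny_fit <- function(x, ...) {
  U <- x$membership
  ids <- rownames(U) %||% as.character(seq_len(nrow(U)))
  tibble(
    id = rep(ids, times = ncol(U)),
    cluster = rep(seq_len(ncol(U)), each = nrow(U)),
    membership = as.numeric(U)
  )
}

#' @export
glance.fanny_fit <- function(x, ...) {
  tibble(
    k = x$k,
    r = x$r,
    objective = x$objective,
    iterations = x$iterations,
    converged = x$converged,
    n_restarts = length(x$restart_objectives),
    n_straddlers = sum(x$hard_labels$straddler)
  )
}

#' @export
tidy.silhouette_report <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.silhouette_report <- function(x, ...) {
  s <- silhouette_summary(x)
  tibble(
    n = nrow(x),
    k = nrow(s$per_cluster),
    overall_silhouette = s$overall,
    min_cluster_silhouette = min(s$per_cluster$mean_s)
  )
}

#' @export
tidy.sweep_result <- function(x, ...) {
  x$table
}

#' @export
glance.sweep_result <- function(x, ...) {
  if (is.null(x$selected)) {
    return(tibble(
      k = NA_integer_, r = NA_real_, mean_silhouette = NA_real_,
      select_rule = x$select_rule, n_cells = nrow(x$table)
    ))
  }
  dplyr::mutate(
    dplyr::select(x$selected, "k", "r", "mean_silhouette"),
    select_rule = x$select_rule,
    n_cells = nrow(x$table)
  )
}
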