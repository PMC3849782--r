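#' Per-object silhouette widths
#'
#' Computes the standard silhouette for a crisp partition of a
#' dissimilarity matrix: `a_i` is the mean dissimilarity of object i to
#' the other members of its cluster, `b_i` the smallest mean dissimilarity
#' to any other cluster, and `s_i = (b_i - a_i) / max(a_i, b_i)`.
#' Members of singleton clusters take `s_i = 0` by convention, as does any
#' object with `max(a_i, b_i) = 0` (coincident points).
#'
#' @param D Symmetric dissimilarity matrix or `dist`.
#' @param labels Integer or factor cluster labels, one per object (or a
#'   tibble with `id` and `cluster` columns as produced by [harden()]).
#' @return An object of class `silhouette_report`: a tibble with columns
#'   `id`, `cluster`, `neighbor` (the cluster attaining `b_i`), `a`, `b`,
#'   `s`.
#' @export
silhouette_samples <- function(D, labels) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  if (is.data.frame(labels)) {
    stopifnot(all(c("id", "cluster") %in% names(labels)))
    labels <- labels$cluster[match(rownames(D), labels$id)]
  }
  if (length(labels) != n) {
    abort("One label per object is required.")
  }
  labels <- as.integer(factor(labels, levels = unique(labels)))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) {
    abort("Silhouette is undefined for a single cluster (k = 1).")
  }
  # mean dissimilarity of every object to every cluster
  member <- outer(labels, clusters, "==")
  sums <- D %*% member
  sizes <- colSums(member)
  own <- match(labels, clusters)
  a <- numeric(n)
  b <- numeric(n)
  neighbor <- integer(n)
  for (i in seq_len(n)) {
    v <- own[i]
    a[i] <- if (sizes[v] > 1) sums[i, v] / (sizes[v] - 1) else NA_real_
    other_means <- sums[i, -v] / sizes[-v]
    j <- which.min(other_means)
    b[i] <- other_means[j]
    neighbor[i] <- clusters[-v][j]
  }
  s <- ifelse(
    is.na(a) | pmax(a, b) == 0,
    0,
    (b - a) / pmax(a, b)
  )
  structure(
    tibble(
      id = rownames(D),
      cluster = labels,
      neighbor = neighbor,
      a = a,
      b = b,
      s = as.numeric(s)
    ),
    class = c("silhouette_report", "tbl_df", "tbl", "data.frame")
  )
}

#' Summarize a silhouette report
#'
#' @param report A `silhouette_report` from [silhouette_samples()].
#' @return A list with `per_cluster` (tibble of `cluster`, `n`, `mean_s`,
#'   `min_s`) and `overall` — the unweighted mean of `s` over objects
#'   (not over clusters), so large clusters carry proportional weight.
#' @export
silhouette_summary <- function(report) {
  stopifnot(inherits(report, "silhouette_report"))
  per_cluster <- dplyr::summarise(
    dplyr::group_by(as_tibble(report), .data$cluster),
    n = dplyr::n(),
    mean_s = mean(.data$s),
    min_s = min(.data$s),
    .groups = "drop"
  )
  list(per_cluster = per_cluster, overall = mean(report$s))
}

#' Sweep cluster number and membership exponent, selecting by silhouette
#'
#' Fits [fanny_fit()] for every (k, r) grid cell, hardens the memberships,
#' scores the crisp partition by silhouette, and selects the
#' silhouette-maximizing cell. The default exponent grid is the canonical
#' eleven-value sweep `1.5, 2, 2.5, 5, 7.5, 8, 8.1, 8.2, 8.5, 9, 10`.
#' Two selection rules are available: `"mean"` maximizes the overall mean
#' silhouette; `"minmax"` maximizes the worst per-cluster mean silhouette,
#' favoring configurations where every cluster is well formed. Ties break
#' toward smaller k, then smaller r. Cells with `k >= n` are skipped with
#' a warning; if every cell is degenerate (e.g. an all-zero dissimilarity
#' matrix) the sweep returns its table flagged, with no selection.
#'
#' @param D Symmetric dissimilarity matrix or `dist`.
#' @param k_grid Integer cluster counts to try (default `2:4`).
#' @param r_grid Membership exponents to try.
#' @param select_rule `"mean"` or `"minmax"`.
#' @param n_restarts,max_iter,tol Passed to [fanny_fit()].
#' @param seed Top-level seed; each cell gets a derived seed so cells are
#'   independently reproducible.
#' @return An object of class `sweep_result`: list with `table` (tibble of
#'   `k`, `r`, `mean_silhouette`, `min_cluster_silhouette`, `objective`,
#'   `converged`, `degenerate`), `selected` (one-row tibble or `NULL`),
#'   `fits` (the per-cell `fanny_fit` objects, named `"k=?,r=?"`) and
#'   `select_rule`.
#' @export
sweep_parameters <- function(D,
                             k_grid = 2:4,
                             r_grid = c(1.5, 2, 2.5, 5, 7.5, 8, 8.1, 8.2, 8.5, 9, 10),
                             select_rule = c("mean", "minmax"),
                             n_restarts = 5, max_iter = 500, tol = 1e-9,
                             seed = NULL) {
  select_rule <- match.arg(select_rule)
  D <- check_dissimilarity(D)
  n <- nrow(D)
  if (length(k_grid) == 0 || length(r_grid) == 0) {
    abort("`k_grid` and `r_grid` must be non-empty.")
  }
  cells <- tidyr::expand_grid(k = sort(unique(as.integer(k_grid))),
                              r = sort(unique(as.numeric(r_grid))))
  drop <- cells$k >= n
  if (any(drop)) {
    warn(sprintf(
      "Skipping %d grid cell(s) with k >= n = %d.", sum(drop), n
    ))
    cells <- cells[!drop, , drop = FALSE]
  }
  if (nrow(cells) == 0) {
    abort("No feasible (k, r) grid cells.")
  }
  fits <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    k <- cells$k[i]
    r <- cells$r[i]
    fit <- fanny_fit(
      D, k = k, r = r, tol = tol, max_iter = max_iter,
      n_restarts = n_restarts, seed = derive_seed(seed, i)
    )
    labels <- fit$hard_labels$cluster
    degenerate <- length(unique(labels)) < 2
    if (degenerate) {
      mean_s <- NA_real_
      min_s <- NA_real_
    } else {
      sil <- silhouette_summary(silhouette_samples(D, labels))
      mean_s <- sil$overall
      min_s <- min(sil$per_cluster$mean_s)
    }
    fits[[i]] <- fit
    rows[[i]] <- tibble(
      k = k, r = r,
      mean_silhouette = mean_s,
      min_cluster_silhouette = min_s,
      objective = fit$objective,
      converged = fit$converged,
      degenerate = degenerate
    )
  }
  table <- dplyr::bind_rows(rows)
  names(fits) <- sprintf("k=%d,r=%g", table$k, table$r)
  stat <- if (select_rule == "mean") {
    table$mean_silhouette
  } else {
    table$min_cluster_silhouette
  }
  selected <- NULL
  if (any(!is.na(stat))) {
    # ties toward smaller k then smaller r: table is sorted that way,
    # which.max takes the first maximum
    best <- which.max(ifelse(is.na(stat), -Inf, stat))
    selected <- table[best, , drop = FALSE]
  } else {
    warn("All grid cells degenerate; no (k, r) selected.")
  }
  structure(
    list(table = table, selected = selected, fits = fits,
         select_rule = select_rule),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %d cell(s), selection rule '%s'\n",
    nrow(x$table), x$select_rule
  ))
  if (is.null(x$selected)) {
    cat("no selection (all cells degenerate)\n")
  } else {
    cat(sprintf(
      "selected k = %d, r = %g (mean silhouette %.4f)\n",
      x$selected$k, x$selected$r, x$selected$mean_silhouette
    ))
  }
  print(x$table)
  invisible(x)
}
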