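#' Dissimilarity-based fuzzy clustering objective
#'
#' Evaluates the FANNY-type objective
#' \deqn{\sum_{v=1}^{k} \frac{\sum_{i,j} u_{iv}^r u_{jv}^r d(i,j)^2}
#'       {\sum_j u_{jv}^r}}
#' where the double sum runs over all ordered pairs (i, j). Note the
#' denominator carries no factor 2: the value reported here is twice the
#' Kaufman–Rousseeuw convention, which rescales the objective without
#' moving its minimizers.
#'
#' @param U An n-by-k membership matrix; rows must sum to 1 (tolerance
#'   1e-9) with entries in \[0, 1\].
#' @param D An n-by-n symmetric dissimilarity matrix (or `dist`).
#' @param r Membership exponent, > 1.
#' @return The objective value (a non-negative scalar).
#' @examples
#' D <- matrix(c(0, 1, 1, 0), 2)
#' fanny_objective(matrix(1, 2, 1), D, r = 2) # (1 + 1) / 2 = 1
#' @export
fanny_objective <- function(U, D, r) {
  D <- check_dissimilarity(D)
  U <- check_membership(U, nrow(D))
  if (r <= 1) {
    abort("Membership exponent `r` must exceed 1.")
  }
  Ur <- U^r
  D2 <- D^2
  num <- colSums(Ur * (D2 %*% Ur))
  den <- colSums(Ur)
  sum(ifelse(den > 0, num / den, 0))
}

check_membership <- function(U, n = NULL) {
  if (!is.matrix(U)) {
    U <- as.matrix(U)
  }
  if (!is.null(n) && nrow(U) != n) {
    abort("Membership matrix rows must match the dissimilarity dimension.")
  }
  if (any(U < -1e-12) || any(U > 1 + 1e-12)) {
    abort("Memberships must lie in [0, 1].")
  }
  if (any(abs(rowSums(U) - 1) > 1e-9)) {
    abort("Membership rows must sum to 1 (tolerance 1e-9).")
  }
  U
}

#' Fit a FANNY-type fuzzy clustering to a dissimilarity matrix
#'
#' Minimizes [fanny_objective()] by an alternating relational fuzzy
#' c-means scheme: each cluster's implicit-centroid distances
#' `a_iv = (D^2 p_v)_i - p_v' D^2 p_v / 2` (with `p_v` the r-th-power
#' membership weights normalized to sum 1) are recomputed from the current
#' memberships, then memberships are refreshed by the closed-form simplex
#' update `u_iv proportional to a_iv^(-1/(r-1))`. For dissimilarities
#' derived from points in Euclidean space each sweep cannot increase the
#' objective; for general symmetric input, negative implicit distances are
#' clamped at zero. Multiple seeded restarts are run and the best local
#' minimum kept. A restart whose membership matrix collapses a cluster
#' (a column with negligible total mass) is rerun from a fresh derived
#' seed and the event reported.
#'
#' @param D Symmetric dissimilarity matrix or `dist` object.
#' @param k Number of clusters, `2 <= k < n`.
#' @param r Membership exponent > 1; larger values give fuzzier
#'   memberships (default 2).
#' @param tol Relative objective-change convergence threshold
#'   (default 1e-9).
#' @param max_iter Maximum sweeps per restart (default 500); hitting it
#'   flags `converged = FALSE` rather than erroring.
#' @param n_restarts Number of random restarts (default 5).
#' @param seed Integer seed making the whole fit deterministic; `NULL`
#'   uses the current RNG stream.
#' @param init `"random_dirichlet"` draws each initial membership row from
#'   a flat Dirichlet; `"spread_medoids"` starts from k maximally spread
#'   objects (deterministic, so restarts beyond the first still randomize).
#' @return An object of class `fanny_fit`: `membership` (n-by-k matrix,
#'   rows named by object id), `objective`, `hard_labels` (tibble from
#'   [harden()]), `iterations`, `converged`, `restart_objectives`,
#'   `trace` (objective sequence of the winning restart), `k`, `r`.
#' @export
fanny_fit <- function(D, k, r = 2, tol = 1e-9, max_iter = 500,
                      n_restarts = 5, seed = NULL,
                      init = c("random_dirichlet", "spread_medoids")) {
  init <- match.arg(init)
  D <- check_dissimilarity(D)
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 1 || k >= n) {
    abort(sprintf("`k` must satisfy 1 <= k < n (got k = %d, n = %d).", k, n))
  }
  if (r <= 1) {
    abort("Membership exponent `r` must exceed 1.")
  }
  with_seed(seed, {
    best <- NULL
    restart_objectives <- numeric(n_restarts)
    for (s in seq_len(n_restarts)) {
      U0 <- init_membership(D, k, if (s == 1) init else "random_dirichlet")
      run <- fanny_sweeps(D, U0, r, tol, max_iter)
      attempts <- 0
      while (run$degenerate && attempts < 5) {
        attempts <- attempts + 1
        inform(sprintf(
          "Restart %d collapsed a cluster; rerunning from a fresh start (%d).",
          s, attempts
        ))
        U0 <- init_membership(D, k, "random_dirichlet")
        run <- fanny_sweeps(D, U0, r, tol, max_iter)
      }
      restart_objectives[s] <- run$objective
      if (is.null(best) || run$objective < best$objective) {
        best <- run
      }
    }
    structure(
      list(
        membership = best$U,
        objective = best$objective,
        hard_labels = harden(best$U),
        iterations = best$iterations,
        converged = best$converged,
        restart_objectives = restart_objectives,
        trace = best$trace,
        k = k,
        r = r
      ),
      class = "fanny_fit"
    )
  })
}

init_membership <- function(D, k, init) {
  n <- nrow(D)
  if (init == "spread_medoids") {
    # Greedy farthest-point medoids; memberships from inverse distances.
    med <- which.max(rowSums(D))
    while (length(med) < k) {
      dmin <- apply(D[, med, drop = FALSE], 1, min)
      med <- c(med, which.max(dmin))
    }
    A <- D[, med, drop = FALSE] + 1e-8
    U <- (1 / A) / rowSums(1 / A)
  } else {
    G <- matrix(-log(runif(n * k)), n, k) # flat Dirichlet rows
    U <- G / rowSums(G)
  }
  rownames(U) <- rownames(D)
  U
}

# One full alternating minimization from a given start.
fanny_sweeps <- function(D, U, r, tol, max_iter) {
  D2 <- D^2
  n <- nrow(D)
  k <- ncol(U)
  trace <- objective_fast(U, D2, r)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # collapse test on the memberships themselves, not their r-th powers
    # (u^r underflows at large r even for healthy clusters)
    if (any(apply(U, 2, max) < 1e-6)) {
      return(list(
        U = U, objective = trace[length(trace)], iterations = iter,
        converged = FALSE, trace = trace, degenerate = TRUE
      ))
    }
    # scale each column to its maximum before powering so the weights
    # p_v = u^r / sum(u^r) stay finite at large r
    Um <- sweep(U, 2, apply(U, 2, max), "/")
    Ur <- Um^r
    den <- colSums(Ur)
    P <- sweep(Ur, 2, den, "/")
    DP <- D2 %*% P
    # a[i, v] = squared distance of object i to cluster v's implicit centroid
    A <- sweep(DP, 2, colSums(P * DP) / 2, "-")
    A[A < 0] <- 0 # exact arithmetic guarantees >= 0 for Euclidean input
    U <- membership_update(A, r)
    obj <- objective_fast(U, D2, r)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1]
    if (abs(prev - obj) <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  degenerate <- any(apply(U, 2, max) < 1e-6)
  list(
    U = U, objective = trace[length(trace)], iterations = iter,
    converged = converged, trace = trace, degenerate = degenerate
  )
}

# Closed-form row-wise minimizer of sum_v u_iv^r a_iv on the simplex.
membership_update <- function(A, r) {
  n <- nrow(A)
  k <- ncol(A)
  U <- matrix(0, n, k, dimnames = dimnames(A))
  zero <- A <= .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    # Object sits on one or more implicit centroids: all mass goes there.
    U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  if (any(!hit)) {
    W <- A[!hit, , drop = FALSE]^(-1 / (r - 1))
    U[!hit, ] <- W / rowSums(W)
  }
  U
}

objective_fast <- function(U, D2, r) {
  Ur <- U^r
  den <- colSums(Ur)
  num <- colSums(Ur * (D2 %*% Ur))
  sum(ifelse(den > 0, num / den, 0))
}

#' Harden a fuzzy membership matrix into crisp labels
#'
#' Assigns each object to its maximum-membership cluster, breaking ties
#' toward the lowest cluster index, and flags "straddlers" — objects whose
#' maximum membership is below `1/k + 0.05`, i.e. barely above the uniform
#' level, indicating the fuzzy assignment does not commit to one cluster.
#'
#' @param U Membership matrix (rows sum to 1).
#' @return A tibble with columns `id`, `cluster` (integer), `membership`
#'   (the row maximum) and `straddler` (logical).
#' @export
harden <- function(U) {
  U <- check_membership(U)
  k <- ncol(U)
  lab <- max.col(U, ties.method = "first")
  mx <- U[cbind(seq_len(nrow(U)), lab)]
  tibble(
    id = rownames(U) %||% as.character(seq_len(nrow(U))),
    cluster = as.integer(lab),
    membership = as.numeric(mx),
    straddler = mx < 1 / k + 0.05
  )
}

#' Brute-force minimizer of the fuzzy objective (test oracle)
#'
#' Independent reference minimizer for tiny instances: exhaustively
#' enumerates per-object memberships on a simplex grid of the given
#' resolution, then polishes the best grid point — together with the
#' uniform membership and a set of random softmax starts — by
#' unconstrained quasi-Newton optimization in softmax coordinates. Only
#' intended for n <= 6, k <= 3.
#'
#' @param D Symmetric dissimilarity matrix, n <= 6.
#' @param k Number of clusters, <= 3.
#' @param r Membership exponent > 1.
#' @param resolution Simplex grid steps per object (default 4, i.e.
#'   memberships on a 0.25 grid).
#' @param n_polish_starts Extra random softmax starts to polish
#'   (default 10).
#' @param seed Seed for the random polish starts.
#' @return A list with `objective` (best value found) and `U` (the
#'   corresponding membership matrix).
#' @export
brute_force_min <- function(D, k, r, resolution = 4, n_polish_starts = 10,
                            seed = NULL) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  if (n > 6) {
    abort("brute_force_min is limited to n <= 6.")
  }
  if (k > 3) {
    abort("brute_force_min is limited to k <= 3.")
  }
  if (r <= 1) {
    abort("Membership exponent `r` must exceed 1.")
  }
  D2 <- D^2
  # All compositions of `resolution` into k parts -> one simplex grid.
  grid <- simplex_grid(k, resolution)
  m <- nrow(grid)
  total <- m^n
  if (total > 4e6) {
    abort(sprintf(
      "Simplex grid too large (%g assignments); lower `resolution`.", total
    ))
  }
  # Batched exhaustive evaluation: decode assignment indices as base-m
  # digits and evaluate the objective for a whole batch with matrix ops.
  Ur_grid <- grid^r
  best_obj <- Inf
  best_assign <- rep(1L, n)
  batch <- 100000L
  for (start in seq(1, total, by = batch)) {
    idxs <- start:min(start + batch - 1, total)
    rem <- idxs - 1
    I <- matrix(0L, length(idxs), n)
    for (p in seq_len(n)) {
      I[, p] <- as.integer(rem %% m) + 1L
      rem <- rem %/% m
    }
    obj <- numeric(length(idxs))
    for (v in seq_len(k)) {
      Uv <- matrix(Ur_grid[I, v], nrow = length(idxs))
      num <- rowSums((Uv %*% D2) * Uv)
      den <- rowSums(Uv)
      obj <- obj + ifelse(den > 0, num / den, 0)
    }
    b <- which.min(obj)
    if (obj[b] < best_obj) {
      best_obj <- obj[b]
      best_assign <- I[b, ]
    }
  }
  starts <- list(
    grid[best_assign, , drop = FALSE],
    matrix(1 / k, n, k)
  )
  with_seed(seed, {
    for (s in seq_len(n_polish_starts)) {
      G <- matrix(-log(runif(n * k)), n, k)
      starts[[length(starts) + 1]] <- G / rowSums(G)
    }
    best_U <- starts[[1]]
    for (U0 in starts) {
      res <- polish_membership(U0, D2, r)
      if (res$objective < best_obj) {
        best_obj <- res$objective
        best_U <- res$U
      }
    }
    rownames(best_U) <- rownames(D)
    list(objective = best_obj, U = best_U)
  })
}

# Lattice points of the (k-1)-simplex with `resolution` steps.
simplex_grid <- function(k, resolution) {
  if (k == 1) {
    return(matrix(1, 1, 1))
  }
  parts <- compositions(resolution, k)
  parts / resolution
}

compositions <- function(total, k) {
  if (k == 1) {
    return(matrix(total, 1, 1))
  }
  out <- list()
  for (first in 0:total) {
    rest <- compositions(total - first, k - 1)
    out[[length(out) + 1]] <- cbind(first, rest)
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}

# BFGS in softmax coordinates; gradient-free objective (numerical grad).
polish_membership <- function(U0, D2, r) {
  n <- nrow(U0)
  k <- ncol(U0)
  z0 <- log(pmax(U0, 1e-8))
  fn <- function(z) {
    Z <- matrix(z, n, k)
    E <- exp(Z - apply(Z, 1, max))
    U <- E / rowSums(E)
    objective_fast(U, D2, r)
  }
  opt <- optim(as.vector(z0), fn, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  Z <- matrix(opt$par, n, k)
  E <- exp(Z - apply(Z, 1, max))
  list(objective = opt$value, U = E / rowSums(E))
}

#' @export
print.fanny_fit <- function(x, ...) {
  sizes <- table(factor(x$hard_labels$cluster, levels = seq_len(x$k)))
  cat(sprintf(
    "<fanny_fit> k = %d, r = %g | objective = %.6g | %s after %d iteration(s)\n",
    x$k, x$r, x$objective,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  cat("hard cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  if (any(x$hard_labels$straddler)) {
    cat(sum(x$hard_labels$straddler), "object(s) straddle clusters\n")
  }
  invisible(x)
}
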