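test_that("objective evaluates the printed formula on hand-checked cases", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  # single cluster, full membership: (1*1*1 + 1*1*1) / (1 + 1) = 1
  expect_equal(fanny_objective(matrix(1, 2, 1), D, r = 2), 1)

  # any membership over an all-zero dissimilarity gives 0
  U <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2, byrow = TRUE)
  expect_equal(fanny_objective(U, matrix(0, 2, 2), r = 2), 0)

  # planted indicator on two zero-diameter pairs: within distances all zero
  blk <- block_dissimilarity(c(2, 2), within = 0, between = 10)
  Uind <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(fanny_objective(Uind, blk$D, r = 2), 0)

  # invalid memberships are rejected
  expect_error(fanny_objective(matrix(c(0.5, 0.2), 1, 2), matrix(0, 1, 1), 2),
               "sum to 1")
  expect_error(fanny_objective(matrix(1, 2, 1), D, r = 1), "exceed 1")
})

test_that("well-separated pairs are recovered with confident memberships", {
  D <- two_pair_dissimilarity()
  fit <- fanny_fit(D, k = 2, r = 2, seed = 5)
  lab <- fit$hard_labels$cluster
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_false(lab[1] == lab[3])
  expect_true(all(fit$hard_labels$membership > 0.95))
  expect_true(fit$converged)

  # matches the independent brute-force minimum
  bf <- brute_force_min(D, k = 2, r = 2, seed = 99)
  expect_lte(fit$objective, bf$objective * (1 + 1e-4))
})

test_that("larger membership exponent gives fuzzier memberships", {
  D <- two_pair_dissimilarity()
  fit2 <- fanny_fit(D, k = 2, r = 2, seed = 5)
  fit10 <- fanny_fit(D, k = 2, r = 10, seed = 5)
  dev2 <- max(abs(fit2$membership - 0.5))
  dev10 <- max(abs(fit10$membership - 0.5))
  expect_lt(dev10, dev2)

  # the independent brute-force optimum fuzzifies the same way, and the
  # two routes land on the same memberships
  bf2 <- brute_force_min(D, k = 2, r = 2, seed = 1)
  bf10 <- brute_force_min(D, k = 2, r = 10, seed = 1)
  expect_lt(max(abs(bf10$U - 0.5)), max(abs(bf2$U - 0.5)))
  expect_equal(max(abs(fit10$membership - 0.5)), max(abs(bf10$U - 0.5)),
               tolerance = 1e-3)
})

test_that("objective trace is non-increasing and rows stay stochastic", {
  set.seed(31)
  for (rep in 1:5) {
    D <- random_euclidean_instance(sample(8:15, 1))
    fit <- fanny_fit(D, k = 3, r = sample(c(1.5, 2, 8.2), 1), seed = rep)
    expect_true(all(diff(fit$trace) <= 1e-12))
    expect_equal(rowSums(fit$membership), setNames(rep(1, nrow(D)), rownames(D)),
                 tolerance = 1e-9)
    expect_true(all(fit$membership >= 0 & fit$membership <= 1))
    expect_equal(fit$objective,
                 fanny_objective(fit$membership, D, fit$r),
                 tolerance = 1e-9)
  }
})

test_that("fits are deterministic given a seed", {
  D <- random_euclidean_instance(10)
  f1 <- fanny_fit(D, k = 2, r = 2, seed = 123)
  f2 <- fanny_fit(D, k = 2, r = 2, seed = 123)
  expect_identical(f1, f2)
  # and the seed sandboxing leaves the caller's RNG stream untouched
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(fanny_fit(D, k = 2, r = 2, seed = 55))
  expect_identical(runif(1), before)
})

test_that("permuting objects permutes hard labels identically", {
  set.seed(77)
  D <- random_euclidean_instance(9)
  perm <- sample(9)
  f <- fanny_fit(D, k = 2, r = 2, seed = 4)
  fp <- fanny_fit(D[perm, perm], k = 2, r = 2, seed = 4)
  agree <- adjusted_rand_index(
    setNames(f$hard_labels$cluster, f$hard_labels$id),
    setNames(fp$hard_labels$cluster, fp$hard_labels$id)
  )
  expect_equal(agree, 1)
})

test_that("degenerate inputs are handled per contract", {
  Z <- matrix(0, 4, 4)
  fit <- fanny_fit(Z, k = 2, r = 2, seed = 1)
  expect_equal(fit$objective, 0)
  expect_true(fit$converged)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 4), tolerance = 1e-9)

  D <- two_pair_dissimilarity()
  expect_error(fanny_fit(D, k = 4, r = 2), "k")
  expect_error(fanny_fit(D, k = 2, r = 1), "exceed 1")

  # non-convergence is flagged, not thrown
  set.seed(8)
  Dr <- random_euclidean_instance(12)
  f1 <- fanny_fit(Dr, k = 3, r = 2, max_iter = 1, n_restarts = 1, seed = 2)
  expect_false(f1$converged)
})

test_that("hardening takes the argmax with low-index ties and flags straddlers", {
  U <- rbind(c(0.8, 0.2), c(0.5, 0.5), c(0.1, 0.9))
  rownames(U) <- c("a", "b", "c")
  h <- harden(U)
  expect_equal(h$cluster, c(1L, 1L, 2L))
  expect_equal(h$straddler, c(FALSE, TRUE, FALSE))

  # column permutation permutes labels consistently
  h2 <- harden(U[, c(2, 1)])
  expect_equal(h2$cluster, c(2L, 1L, 1L))
})

test_that("fanny_fit agrees with the brute-force oracle over random instances", {
  set.seed(2024)
  n_cases <- 0
  for (rep in 1:7) {
    n <- sample(4:6, 1)
    D <- random_euclidean_instance(n)
    for (r in c(1.5, 2, 8.2)) {
      n_cases <- n_cases + 1
      fit <- fanny_fit(D, k = 2, r = r, seed = rep)
      bf <- brute_force_min(D, k = 2, r = r, seed = rep + 500)
      expect_lte(fit$objective,
                 bf$objective + 1e-4 * max(bf$objective, 1e-12))
      expect_true(all(diff(fit$trace) <= 1e-12))
    }
  }
  expect_gte(n_cases, 20)
})

test_that("brute force solves tiny instances to their known optima", {
  # two points, two clusters: splitting them drives the objective to ~0
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  bf <- brute_force_min(D, k = 2, r = 2, resolution = 10, seed = 1)
  expect_lt(bf$objective, 1e-6)
  expect_equal(sort(round(bf$U[1, ])), c(0, 1))

  expect_error(brute_force_min(random_euclidean_instance(7), 2, 2), "n <= 6")
  expect_error(brute_force_min(random_euclidean_instance(4), 4, 2), "k <= 3")
})

test_that("tidy and glance expose membership and fit summaries", {
  D <- two_pair_dissimilarity()
  fit <- fanny_fit(D, k = 2, r = 2, seed = 5)
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_setequal(unique(td$id), rownames(D))
  expect_equal(
    sum(td$membership[td$id == "p1"]), 1, tolerance = 1e-9
  )
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_true(gl$converged)
})
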