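test_that("n-peptide counting covers all overlapping windows", {
  expect_equal(count_npeptides("AAAC", 1), c(A = 3L, C = 1L))
  expect_equal(count_npeptides("ACDE", 2), c(AC = 1L, CD = 1L, DE = 1L))
  expect_length(count_npeptides("AC", 3), 0) # shorter than the window
})

test_that("ambiguity policy skips or rejects non-standard windows", {
  # X kills the windows covering it, in numerator and denominator alike
  expect_equal(count_npeptides("AXA", 1), c(A = 2L))
  expect_equal(count_npeptides("AXAA", 2), c(AA = 1L))
  expect_error(count_npeptides("AXA", 1, ambiguity_policy = "error"), "position 2")
})

test_that("counting agrees with naive window enumeration on random sequences", {
  set.seed(101)
  alphabet <- c("A", "C", "D", "E", "G", "X")
  for (rep in 1:20) {
    L <- sample(5:50, 1)
    s <- paste(sample(alphabet, L, replace = TRUE), collapse = "")
    for (n in 1:4) {
      naive <- table(Filter(
        function(w) !grepl("X", w),
        vapply(seq_len(max(L - n + 1, 0)),
               function(i) substr(s, i, i + n - 1), "")
      ))
      got <- count_npeptides(s, n)
      expect_equal(length(got), length(naive))
      if (length(got) > 0) {
        expect_mapequal(as.list(got), as.list(setNames(as.integer(naive), names(naive))))
      }
    }
  }
})

test_that("block normalization scales counts to total mass base^n", {
  expect_equal(normalize_block(c(A = 3L, C = 1L), 1), c(A = 7.5, C = 2.5))
  b2 <- normalize_block(c(AC = 1L, CD = 1L, DE = 1L), 2)
  expect_equal(unname(b2), rep(100 / 3, 3))
  expect_length(normalize_block(setNames(integer(0), character(0)), 4), 0)
})

test_that("non-empty block sums equal 10^n (property over random sequences)", {
  set.seed(202)
  cfg <- encoder_config()
  for (rep in 1:50) {
    L <- sample(4:120, 1)
    s <- paste(sample(c(AA_letters <- c(
      "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
    )), L, replace = TRUE), collapse = "")
    fv <- encode_sequence(s, "x", config = cfg)
    sums <- tapply(fv$value[fv$block != "domain"],
                   fv$block[fv$block != "domain"], sum)
    for (n in 1:4) {
      blk <- sprintf("n%d", n)
      if (blk %in% names(sums)) {
        expect_equal(unname(sums[blk]), 10^n, tolerance = 1e-12)
      }
    }
  }
})

test_that("domain block holds weight * count per model", {
  fv <- encode_sequence("AAAC", "s1",
                        domain_models = c("CXC", "CXC", "PF-B"))
  dom <- fv[fv$block == "domain", ]
  expect_equal(setNames(dom$value, dom$feature)[c("CXC", "PF-B")],
               c(CXC = 200, `PF-B` = 100))
  # n = 3 block of AAAC: two windows AAA, AAC at 500 each
  n3 <- fv[fv$block == "n3", ]
  expect_equal(setNames(n3$value, n3$feature), c(AAA = 500, AAC = 500))

  none <- encode_sequence("AAAC", "s2")
  expect_equal(nrow(none[none$block == "domain", ]), 0)
})

test_that("feature space is deterministic and vectors are per-sequence", {
  recs <- tibble::tibble(id = c("a", "b"), sequence = c("AC", "CA"))
  fm <- build_feature_matrix(recs, config = encoder_config(peptide_lengths = 1:2))
  M <- as.matrix(fm)
  expect_equal(M["a", "n1:A"], 5)
  expect_equal(M["a", "n1:C"], 5)
  expect_equal(M["b", "n1:A"], 5)

  # adding a record leaves existing stored block values unchanged
  recs3 <- dplyr::bind_rows(recs, tibble::tibble(id = "c", sequence = "WWWW"))
  fm3 <- build_feature_matrix(recs3, config = encoder_config(peptide_lengths = 1:2))
  old <- dplyr::arrange(fm$features, .data$owner_id, .data$block, .data$feature)
  new <- dplyr::arrange(
    dplyr::filter(fm3$features, .data$owner_id %in% c("a", "b")),
    .data$owner_id, .data$block, .data$feature
  )
  expect_equal(old$value, new$value)

  expect_error(build_feature_matrix(recs[1, ]), "2")
})

test_that("encoding is invariant to record order and duplicates encode equally", {
  set.seed(7)
  recs <- tibble::tibble(
    id = paste0("s", 1:4),
    sequence = vapply(1:4, function(i) {
      paste(sample(c("A", "C", "D", "E", "M", "K"), 30, TRUE), collapse = "")
    }, "")
  )
  recs$sequence[4] <- recs$sequence[1] # duplicate sequence content
  fm <- build_feature_matrix(recs)
  M <- as.matrix(fm)
  expect_equal(unname(M["s1", ]), unname(M["s4", ]))

  perm <- recs[c(3, 1, 4, 2), ]
  Mp <- as.matrix(build_feature_matrix(perm))
  expect_equal(Mp[rownames(M), colnames(M)], M)
})

test_that("longer k-mer blocks carry more total mass (weighting intent)", {
  set.seed(11)
  s <- paste(sample(c("A", "C", "D", "E", "G", "M"), 80, TRUE), collapse = "")
  fv <- encode_sequence(s, "x")
  mass <- tapply(fv$value, fv$block, sum)
  expect_true(mass[["n4"]] > mass[["n3"]])
  expect_true(mass[["n3"]] > mass[["n2"]])
  expect_true(mass[["n2"]] > mass[["n1"]])
  expect_equal(unname(mass[["n4"]] / mass[["n1"]]), 1000)
})

test_that("dissimilarity matrix is symmetric, zero-diagonal, permutation-equivariant", {
  recs <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c("ACDEACDE", "ACDEACDA", "WWWWYYYY")
  )
  fm <- build_feature_matrix(recs)
  D <- dissimilarity_matrix(fm)
  expect_equal(unclass(D), t(unclass(D)))
  expect_equal(diag(D), setNames(rep(0, 3), recs$id))
  expect_true(D["a", "b"] < D["a", "c"]) # similar sequences are closer

  Dp <- dissimilarity_matrix(build_feature_matrix(recs[c(2, 3, 1), ]))
  expect_equal(unclass(Dp)[rownames(D), colnames(D)], unclass(D))

  # identical vectors at distance zero; disjoint 1-mer singletons at sqrt(200)
  recs2 <- tibble::tibble(id = c("x", "y", "z"), sequence = c("AAAA", "AAAA", "CCCC"))
  D2 <- dissimilarity_matrix(
    build_feature_matrix(recs2, config = encoder_config(peptide_lengths = 1L))
  )
  expect_equal(D2["x", "y"], 0)
  expect_equal(D2["x", "z"], sqrt(200))

  Dm <- dissimilarity_matrix(
    build_feature_matrix(recs2, config = encoder_config(peptide_lengths = 1L)),
    metric = "manhattan"
  )
  expect_equal(Dm["x", "z"], 20)
})
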