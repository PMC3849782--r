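test_that("generated family sets honor the cardinality and determinism contracts", {
  spec <- family_spec(n_families = 2, seqs_per_family = 20, seed = 42)
  fam <- generate_family_set(spec)
  expect_equal(nrow(fam$records), 40)
  expect_equal(nrow(fam$truth), 40)
  expect_equal(sort(unique(fam$truth$family)), 1:2)
  # two distinct architectures: family-specific models differ
  archs <- split(fam$domain_hits$domain_model, fam$domain_hits$sequence_id)
  models_by_family <- lapply(split(fam$truth$id, fam$truth$family), function(ids) {
    sort(unique(unlist(archs[ids])))
  })
  expect_false(identical(models_by_family[[1]], models_by_family[[2]]))
  expect_true(all(fam$domain_hits$e_value < 1))

  fam2 <- generate_family_set(spec)
  expect_identical(fam, fam2)

  expect_error(family_spec(length_range = c(2, 10)), "min >= 4")
  expect_error(family_spec(n_families = 1), "at least 2")
})

test_that("zero within-family noise collapses members onto their ancestor", {
  fam <- generate_family_set(
    family_spec(seqs_per_family = 4, within_noise = 0, seed = 3)
  )
  by_fam <- split(fam$records$sequence, fam$truth$family)
  for (seqs in by_fam) {
    expect_length(unique(seqs), 1)
  }
  # pairwise within-family feature distance is exactly zero
  fm <- build_feature_matrix(fam$records, fam$domain_hits)
  D <- dissimilarity_matrix(fm)
  ids1 <- fam$truth$id[fam$truth$family == 1]
  expect_equal(max(D[ids1, ids1]), 0)
})

test_that("family ancestors diverge at the requested rate", {
  fam <- generate_family_set(
    family_spec(seqs_per_family = 1, within_noise = 0, seed_divergence = 0.5,
                length_range = c(2000, 2000), seed = 9)
  )
  a <- strsplit(fam$records$sequence[1], "")[[1]]
  b <- strsplit(fam$records$sequence[2], "")[[1]]
  expect_equal(mean(a != b), 0.5, tolerance = 0.1)
})

test_that("adjusted Rand index behaves at its reference points", {
  truth <- tibble::tibble(id = sprintf("s%02d", 1:40),
                          family = rep(1:2, each = 20))
  expect_equal(
    adjusted_rand_index(truth, setNames(truth$family, truth$id)), 1
  )
  # label renaming is irrelevant
  expect_equal(
    adjusted_rand_index(truth, setNames(3 - truth$family, truth$id)), 1
  )
  # all-in-one-cluster carries no information
  expect_equal(
    adjusted_rand_index(truth, setNames(rep(1, 40), truth$id)), 0
  )
  # random labels hover near zero
  set.seed(1234)
  aris <- replicate(100, adjusted_rand_index(
    truth, setNames(sample(1:2, 40, TRUE), truth$id)
  ))
  expect_lt(max(abs(aris)), 0.35)
  expect_lt(abs(mean(aris)), 0.05)

  expect_error(
    adjusted_rand_index(truth, setNames(rep(1, 3), c("a", "b", "c"))),
    "same ids"
  )
})

test_that("planted EST tables round-trip through profile counting", {
  truth <- tibble::tibble(id = sprintf("g%02d", 1:20),
                          family = rep(c("I", "II"), each = 10))
  gen <- generate_est_table(truth, hits_per_gene = 3, redundancy_rate = 0.6,
                            sharing_rate = 0.2, seed = 77)
  res <- est_profile_table(gen$hits)
  expect_equal(res$profiles$redundant,
               gen$expected$redundant[match(res$profiles$group_label,
                                            gen$expected$group_label)])
  expect_equal(res$profiles$unique,
               gen$expected$unique[match(res$profiles$group_label,
                                         gen$expected$group_label)])
  expect_equal(res$overlap$common[res$overlap$category == "redundant"],
               gen$expected$common_redundant[1])
  expect_equal(res$overlap$common[res$overlap$category == "unique"],
               gen$expected$common_unique[1])
})

test_that("degenerate EST generator rates behave as planted", {
  truth <- tibble::tibble(id = sprintf("g%02d", 1:10),
                          family = rep(c("I", "II"), each = 5))
  all_unique <- generate_est_table(truth, redundancy_rate = 0, seed = 5)
  res <- est_profile_table(all_unique$hits)
  expect_equal(sum(res$profiles$redundant), 0)

  no_common <- generate_est_table(truth, sharing_rate = 0, seed = 5)
  res2 <- est_profile_table(no_common$hits)
  expect_equal(res2$overlap$common, c(0, 0))
})

test_that("clustering difficulty rises with within-family noise", {
  mean_ari <- vapply(c(0.05, 0.4), function(noise) {
    aris <- vapply(1:3, function(s) {
      fam <- generate_family_set(family_spec(
        seqs_per_family = 6, within_noise = noise,
        length_range = c(60, 80), seed = 1000 + s
      ))
      fm <- build_feature_matrix(fam$records, fam$domain_hits)
      fit <- fanny_fit(dissimilarity_matrix(fm), k = 2, r = 2, seed = s,
                       n_restarts = 2)
      adjusted_rand_index(fam$truth, fit$hard_labels)
    }, 0)
    mean(aris)
  }, 0)
  expect_gte(mean_ari[1], mean_ari[2] - 1e-9)
})

test_that("disabling the k-mer channel leaves domains to separate families", {
  fam <- generate_family_set(family_spec(
    seqs_per_family = 6, use_kmer_signal = FALSE, within_noise = 0, seed = 8
  ))
  fm <- build_feature_matrix(fam$records, fam$domain_hits)
  fit <- fanny_fit(dissimilarity_matrix(fm), k = 2, r = 2, seed = 2)
  expect_equal(adjusted_rand_index(fam$truth, fit$hard_labels), 1)
})
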