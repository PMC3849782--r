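#' Specification for a synthetic protein-family set
#'
#' Describes a multi-subfamily protein set with planted structure. Each
#' family descends from its own random ancestor; members are per-site
#' mutated copies. Family signal travels through two channels, mirroring
#' real subfamily data: k-mer content (divergent ancestors) and domain
#' architecture (per-family model sets). Either channel can be switched
#' off to probe its separate contribution.
#'
#' Defaults represent a clearly resolvable two-subfamily set: two families
#' of 20 members, lengths 300–500 residues, ancestors differing at half of
#' all sites, members differing from their ancestor at 5% of sites, and
#' all families sharing a two-copy "CXC" domain plus one family-specific
#' model — the architecture pattern of CPP-like families.
#'
#' @param n_families Number of families (>= 2, default 2).
#' @param seqs_per_family Members per family (default 20).
#' @param length_range Ancestor length range in residues (default
#'   `c(300, 500)`; minimum 4 so all k-mer blocks are populated).
#' @param seed_divergence Per-site substitution probability between family
#'   ancestors (default 0.5).
#' @param within_noise Per-site substitution probability within a family
#'   (default 0.05).
#' @param domain_models Per-family named integer vectors (model ->
#'   copies), or `NULL` for the default architecture; set
#'   `use_domains = FALSE` to drop the channel entirely.
#' @param use_domains,use_kmer_signal Toggles for the two signal channels
#'   (when `use_kmer_signal = FALSE` all families share one ancestor, so
#'   only domains separate them).
#' @param aa_frequencies Optional sampling weights over the 20 standard
#'   letters (default uniform; no claim of biological realism).
#' @param seed Integer seed; generation is deterministic given it.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_families = 2, seqs_per_family = 20,
                        length_range = c(300, 500),
                        seed_divergence = 0.5, within_noise = 0.05,
                        domain_models = NULL,
                        use_domains = TRUE, use_kmer_signal = TRUE,
                        aa_frequencies = NULL, seed = 1) {
  if (n_families < 2) {
    abort("`n_families` must be at least 2.")
  }
  if (length(length_range) != 2 || length_range[1] < 4 ||
      length_range[1] > length_range[2]) {
    abort("`length_range` must be (min, max) with min >= 4.")
  }
  if (seed_divergence < 0 || seed_divergence > 1 ||
      within_noise < 0 || within_noise > 1) {
    abort("Substitution probabilities must lie in [0, 1].")
  }
  if (is.null(domain_models)) {
    domain_models <- purrr::map(seq_len(n_families), function(f) {
      setNames(c(2L, 1L), c("CXC", sprintf("FAM%d_dom", f)))
    })
  }
  if (length(domain_models) != n_families) {
    abort("`domain_models` needs one entry per family.")
  }
  if (!is.null(aa_frequencies)) {
    stopifnot(length(aa_frequencies) == 20, all(aa_frequencies >= 0))
  }
  structure(
    list(
      n_families = as.integer(n_families),
      seqs_per_family = as.integer(seqs_per_family),
      length_range = as.integer(length_range),
      seed_divergence = seed_divergence,
      within_noise = within_noise,
      domain_models = domain_models,
      use_domains = isTRUE(use_domains),
      use_kmer_signal = isTRUE(use_kmer_signal),
      aa_frequencies = aa_frequencies,
      seed = as.integer(seed)
    ),
    class = "family_spec"
  )
}

#' Generate a synthetic family set with planted truth
#'
#' @param spec A [family_spec()].
#' @return A list with `records` (sequence tibble: `id`, `sequence`,
#'   `description`), `domain_hits` (tibble shaped like
#'   [read_domain_hits()] output, E-values < 1) and `truth` (tibble `id`,
#'   `family` — the planted labels).
#' @examples
#' fam <- generate_family_set(family_spec(seqs_per_family = 5, seed = 7))
#' table(fam$truth$family)
#' @export
generate_family_set <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  probs <- spec$aa_frequencies
  if (!is.null(probs)) {
    probs <- probs / sum(probs)
  }
  sample_aa <- function(n) {
    sample(AA_STANDARD, n, replace = TRUE, prob = probs)
  }
  with_seed(spec$seed, {
    # family ancestors: family 1 is random; others are per-site mutated
    # copies of it at rate seed_divergence (substitution to a different
    # letter, so expected divergence equals the rate)
    base_len <- sample(spec$length_range[1]:spec$length_range[2], 1)
    ancestors <- vector("list", spec$n_families)
    ancestors[[1]] <- sample_aa(base_len)
    for (f in seq_len(spec$n_families)[-1]) {
      if (spec$use_kmer_signal) {
        ancestors[[f]] <- mutate_sites(
          ancestors[[1]], spec$seed_divergence, sample_aa
        )
      } else {
        ancestors[[f]] <- ancestors[[1]]
      }
    }
    records <- list()
    hits <- list()
    truth <- list()
    for (f in seq_len(spec$n_families)) {
      for (m in seq_len(spec$seqs_per_family)) {
        id <- sprintf("F%02dS%03d", f, m)
        member <- mutate_sites(ancestors[[f]], spec$within_noise, sample_aa)
        records[[id]] <- tibble(
          id = id,
          sequence = paste(member, collapse = ""),
          description = sprintf("synthetic family %d member %d", f, m)
        )
        truth[[id]] <- tibble(id = id, family = f)
        if (spec$use_domains) {
          arch <- spec$domain_models[[f]]
          models <- rep(names(arch), arch)
          L <- length(member)
          width <- 46L # nominal CXC-like domain width
          starts <- sort(sample(seq_len(max(1L, L - width)), length(models)))
          hits[[id]] <- tibble(
            sequence_id = id,
            domain_model = models,
            e_value = runif(length(models), 1e-10, 0.9),
            start = as.integer(starts),
            end = as.integer(pmin(starts + width - 1L, L))
          )
        }
      }
    }
    list(
      records = dplyr::bind_rows(records),
      domain_hits = if (length(hits) > 0) {
        dplyr::bind_rows(hits)
      } else {
        tibble(
          sequence_id = character(), domain_model = character(),
          e_value = double(), start = integer(), end = integer()
        )
      },
      truth = dplyr::bind_rows(truth)
    )
  })
}

mutate_sites <- function(letters_vec, rate, sample_aa) {
  if (rate <= 0) {
    return(letters_vec)
  }
  hit <- runif(length(letters_vec)) < rate
  if (any(hit)) {
    # substitute with a letter different from the current one
    repl <- sample_aa(sum(hit))
    same <- repl == letters_vec[hit]
    while (any(same)) {
      repl[same] <- sample_aa(sum(same))
      same <- repl == letters_vec[hit]
    }
    letters_vec[hit] <- repl
  }
  letters_vec
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a planted truth and an inferred
#' partition: 1 for identical partitions (up to label renaming), about 0
#' for random assignment.
#'
#' @param truth Tibble (`id`, `family`) or a named vector of labels.
#' @param labels Tibble (`id`, `cluster`) — e.g. from [harden()] — or a
#'   named vector. Ids must match `truth` exactly (any order).
#' @return The adjusted Rand index, a scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(truth, labels) {
  t_vec <- as_label_vector(truth, c("family", "label", "cluster"))
  l_vec <- as_label_vector(labels, c("cluster", "label", "family"))
  if (!setequal(names(t_vec), names(l_vec))) {
    abort("`truth` and `labels` must cover the same ids.")
  }
  l_vec <- l_vec[names(t_vec)]
  as.numeric(mclust::adjustedRandIndex(t_vec, l_vec))
}

as_label_vector <- function(x, candidates) {
  if (is.data.frame(x)) {
    col <- intersect(candidates, names(x))
    if (length(col) == 0 || !"id" %in% names(x)) {
      abort(sprintf(
        "Label data frame needs an `id` column and one of: %s",
        paste(candidates, collapse = ", ")
      ))
    }
    setNames(x[[col[1]]], x$id)
  } else {
    if (is.null(names(x))) {
      abort("Label vectors must be named by object id.")
    }
    x
  }
}

#' Generate an EST hit table with planted profile counts
#'
#' Builds a synthetic EST-to-gene alignment table whose redundant/unique
#' composition and cross-group overlap are planted exactly, so that
#' profile counting can be verified by round-trip. Genes are the ids in
#' `truth`; groups are the planted families. Per group, the number of ESTs
#' is `round(hits_per_gene * n_genes)`; a fraction `redundancy_rate` of
#' them are redundant (two alignment records to random genes of the
#' group), the rest unique (one record). A fraction `sharing_rate` of the
#' smaller group's redundant (resp. unique) count is made common to both
#' groups by reusing EST ids across groups.
#'
#' @param truth Tibble (`id`, `family`) of gene ids and their groups.
#' @param hits_per_gene Expected ESTs per gene (default 3).
#' @param redundancy_rate Fraction of each group's ESTs that are redundant
#'   (default 0.5).
#' @param sharing_rate Fraction of the smaller group's redundant/unique
#'   ESTs shared across groups (default 0.1).
#' @param seed Integer seed.
#' @return A list with `hits` (tibble `est_id`, `gene_id`, `group_label`,
#'   `e_value`) and `expected` — the planted counts: tibble of
#'   `group_label`, `redundant`, `unique`, plus attributes-free columns
#'   `common_redundant`, `common_unique` repeated on each row.
#' @export
generate_est_table <- function(truth, hits_per_gene = 3,
                               redundancy_rate = 0.5, sharing_rate = 0.1,
                               seed = NULL) {
  stopifnot(all(c("id", "family") %in% names(truth)))
  if (redundancy_rate < 0 || redundancy_rate > 1 ||
      sharing_rate < 0 || sharing_rate > 1) {
    abort("Rates must lie in [0, 1].")
  }
  groups <- split(truth$id, truth$family)
  labels <- names(groups)
  n_est <- vapply(groups, function(g) {
    max(1L, as.integer(round(hits_per_gene * length(g))))
  }, 1L)
  n_red <- as.integer(round(redundancy_rate * n_est))
  n_unq <- n_est - n_red
  common_red <- as.integer(round(sharing_rate * min(n_red)))
  common_unq <- as.integer(round(sharing_rate * min(n_unq)))
  with_seed(seed, {
    rows <- list()
    # shared EST ids appear (with the same classification) in every group
    shared_red <- sprintf("EST_SR%04d", seq_len(common_red))
    shared_unq <- sprintf("EST_SU%04d", seq_len(common_unq))
    for (gi in seq_along(labels)) {
      g <- labels[gi]
      genes <- groups[[g]]
      own_red <- if (n_red[gi] > common_red) {
        sprintf("EST_%s_R%04d", g, seq_len(n_red[gi] - common_red))
      } else {
        character(0)
      }
      own_unq <- if (n_unq[gi] > common_unq) {
        sprintf("EST_%s_U%04d", g, seq_len(n_unq[gi] - common_unq))
      } else {
        character(0)
      }
      red_ids <- c(shared_red, own_red)
      unq_ids <- c(shared_unq, own_unq)
      pick_gene <- function(n) sample(genes, n, replace = TRUE)
      rows[[g]] <- dplyr::bind_rows(
        tibble( # redundant: two records each
          est_id = rep(red_ids, each = 2),
          gene_id = pick_gene(2 * length(red_ids)),
          group_label = g
        ),
        tibble(
          est_id = unq_ids,
          gene_id = pick_gene(length(unq_ids)),
          group_label = g
        )
      )
    }
    hits <- dplyr::bind_rows(rows)
    hits$e_value <- 10^runif(nrow(hits), -50, -6) # all below typical cutoffs
    expected <- tibble(
      group_label = labels,
      redundant = unname(n_red),
      unique = unname(n_unq),
      common_redundant = common_red,
      common_unique = common_unq
    )
    list(hits = hits, expected = expected)
  })
}
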