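#' Encoder configuration
#'
#' Bundles the parameters of the feature encoding: which peptide lengths to
#' count, the weight base (each length-n block is scaled to total mass
#' `base^n`, so longer, more specific peptides dominate the geometry), the
#' weight applied to raw domain counts, how k-mer windows containing
#' ambiguity letters are treated, and the dissimilarity metric.
#'
#' @param peptide_lengths Strictly increasing positive integers; default
#'   `1:4` (mono- to tetra-peptides).
#' @param peptide_weight_base Positive real `w` such that the length-n
#'   block sums to `w^n`; default 10.
#' @param domain_weight Positive real multiplier on per-model domain
#'   counts; default 100.
#' @param ambiguity_policy `"skip"` drops windows containing a non-standard
#'   letter (B, Z, X, U, O) from both numerator and denominator of the
#'   normalization; `"error"` fails on the first such letter.
#' @param metric Dissimilarity between embedded feature vectors:
#'   `"euclidean"` (default) or `"manhattan"`.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(peptide_lengths = 1:4,
                           peptide_weight_base = 10,
                           domain_weight = 100,
                           ambiguity_policy = c("skip", "error"),
                           metric = c("euclidean", "manhattan")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  metric <- match.arg(metric)
  peptide_lengths <- as.integer(peptide_lengths)
  if (length(peptide_lengths) == 0 || any(peptide_lengths < 1)) {
    abort("`peptide_lengths` must be positive integers.")
  }
  if (is.unsorted(peptide_lengths, strictly = TRUE)) {
    abort("`peptide_lengths` must be strictly increasing.")
  }
  if (peptide_weight_base <= 0 || domain_weight <= 0) {
    abort("Weights must be positive.")
  }
  structure(
    list(
      peptide_lengths = peptide_lengths,
      peptide_weight_base = peptide_weight_base,
      domain_weight = domain_weight,
      ambiguity_policy = ambiguity_policy,
      metric = metric
    ),
    class = "encoder_config"
  )
}

#' Count overlapping n-peptides in a sequence
#'
#' Counts all `L - n + 1` overlapping windows of length `n`. Windows
#' containing any non-standard letter are skipped (default) or raise an
#' error, per the policy; skipped windows count toward neither the
#' numerator nor the denominator of the downstream normalization.
#'
#' @param sequence A single upper-case amino-acid string.
#' @param n Window length (>= 1).
#' @param ambiguity_policy `"skip"` or `"error"`.
#' @return A named integer vector of counts over the observed n-peptides
#'   (empty when the sequence is shorter than `n` or no window is
#'   standard).
#' @examples
#' count_npeptides("AAAC", 1)
#' count_npeptides("ACDE", 2)
#' @export
count_npeptides <- function(sequence, n, ambiguity_policy = c("skip", "error")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  stopifnot(is.character(sequence), length(sequence) == 1, n >= 1)
  n <- as.integer(n)
  if (ambiguity_policy == "error") {
    bad <- regexpr(sprintf("[%s]", paste(AA_AMBIGUOUS, collapse = "")), sequence)
    if (bad > 0) {
      abort(sprintf(
        "Ambiguity letter '%s' at position %d (policy 'error').",
        substr(sequence, bad, bad), bad
      ))
    }
  }
  L <- nchar(sequence)
  if (L < n) {
    return(setNames(integer(0), character(0)))
  }
  windows <- substring(sequence, seq_len(L - n + 1L), n:L)
  std <- sprintf("^[%s]+$", paste(AA_STANDARD, collapse = ""))
  windows <- windows[grepl(std, windows)]
  if (length(windows) == 0) {
    return(setNames(integer(0), character(0)))
  }
  tab <- table(windows)
  setNames(as.integer(tab), names(tab))
}

#' Normalize an n-peptide count block
#'
#' Converts raw counts `f_i` into weighted normalized frequencies
#' `A_i = w^n * f_i / sum_j f_j`, where the denominator runs over the same
#' counted windows of this sequence. A non-empty block therefore sums to
#' `w^n` exactly; an empty count vector yields an empty block.
#'
#' @param counts Named counts from [count_npeptides()].
#' @param n The peptide length of the block.
#' @param base The weight base `w` (default 10, giving block masses
#'   10, 100, 1000, 10000 for n = 1..4).
#' @return A named numeric vector of weighted frequencies.
#' @examples
#' normalize_block(c(A = 3L, C = 1L), 1) # A: 7.5, C: 2.5
#' @export
normalize_block <- function(counts, n, base = 10) {
  if (length(counts) == 0) {
    return(setNames(numeric(0), character(0)))
  }
  base^n * counts / sum(counts)
}

#' Encode one protein as a weighted k-mer + domain-count feature vector
#'
#' Builds the per-sequence feature blocks: for each configured peptide
#' length `n`, normalized k-mer frequencies scaled to total mass
#' `base^n`; plus one domain block holding `domain_weight * count` for
#' each domain model hitting the sequence (counts, not presence — a model
#' occurring twice contributes twice the weight).
#'
#' @param sequence Upper-case amino-acid string.
#' @param id Sequence identifier (becomes `owner_id`).
#' @param domain_models Character vector of domain-model names hitting this
#'   sequence, one entry per hit (already E-value filtered).
#' @param config An [encoder_config()].
#' @return A tibble with columns `owner_id`, `block` (`"n1"`, `"n2"`, ...
#'   or `"domain"`), `feature` and `value`, sparse over observed features.
#' @export
encode_sequence <- function(sequence, id, domain_models = character(),
                            config = encoder_config()) {
  stopifnot(inherits(config, "encoder_config"))
  kmer_blocks <- purrr::map(config$peptide_lengths, function(n) {
    counts <- count_npeptides(sequence, n, config$ambiguity_policy)
    vals <- normalize_block(counts, n, config$peptide_weight_base)
    tibble(
      block = sprintf("n%d", n),
      feature = names(vals),
      value = as.numeric(vals)
    )
  })
  dom <- table(domain_models)
  dom_block <- tibble(
    block = rep("domain", length(dom)),
    feature = names(dom),
    value = config$domain_weight * as.numeric(dom)
  )
  out <- dplyr::bind_rows(c(kmer_blocks, list(dom_block)))
  dplyr::mutate(out, owner_id = id, .before = 1)
}

#' Build the feature matrix for a sequence collection
#'
#' Encodes every record and derives the deterministic global feature space
#' (the union of observed feature keys, ordered by block then key) into
#' which each sparse vector embeds with absent coordinates equal to zero.
#' Per-sequence block values are independent of which other records are
#' present, so adding a record never changes existing vectors.
#'
#' @param records Sequence tibble from [read_fasta()] (columns `id`,
#'   `sequence`).
#' @param hits Optional domain-hit tibble from [read_domain_hits()]
#'   (columns `sequence_id`, `domain_model`), already E-value filtered.
#' @param config An [encoder_config()].
#' @return An object of class `feature_matrix`: a list with `space`
#'   (tibble of `block`, `feature` in embedding order), `features` (long
#'   tibble of all per-sequence values), `ids` and `config`. Use
#'   [as.matrix.feature_matrix()] for the dense embedding.
#' @export
build_feature_matrix <- function(records, hits = NULL, config = encoder_config()) {
  if (nrow(records) < 2) {
    abort("At least 2 sequence records are required.")
  }
  if (anyDuplicated(records$id)) {
    abort("Sequence ids must be unique.")
  }
  hit_models <- if (is.null(hits) || nrow(hits) == 0) {
    list()
  } else {
    split(hits$domain_model, hits$sequence_id)
  }
  features <- purrr::pmap(
    list(records$sequence, records$id),
    function(seq, id) {
      encode_sequence(seq, id, hit_models[[id]] %||% character(), config)
    }
  )
  features <- dplyr::bind_rows(features)
  block_order <- c(sprintf("n%d", config$peptide_lengths), "domain")
  space <- dplyr::arrange(
    dplyr::distinct(features, .data$block, .data$feature),
    match(.data$block, block_order), .data$feature
  )
  structure(
    list(
      space = space,
      features = features,
      ids = records$id,
      config = config
    ),
    class = "feature_matrix"
  )
}

#' @describeIn build_feature_matrix Dense embedding: one row per sequence,
#'   one column per feature key, absent coordinates zero.
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @export
as.matrix.feature_matrix <- function(x, ...) {
  key <- paste(x$space$block, x$space$feature, sep = ":")
  i <- match(x$features$owner_id, x$ids)
  j <- match(paste(x$features$block, x$features$feature, sep = ":"), key)
  M <- Matrix::sparseMatrix(
    i = i, j = j, x = x$features$value,
    dims = c(length(x$ids), length(key)),
    dimnames = list(x$ids, key)
  )
  as.matrix(M)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d sequences, %d features (%s)\n",
    length(x$ids), nrow(x$space),
    paste(sprintf(
      "%s: %d", unique(x$space$block),
      as.integer(table(x$space$block)[unique(x$space$block)])
    ), collapse = ", ")
  ))
  invisible(x)
}

#' Pairwise dissimilarity matrix over encoded sequences
#'
#' Embeds the sparse vectors into the common feature space and computes
#' pairwise dissimilarities (euclidean by default; manhattan optional).
#' The result is symmetric with a zero diagonal and carries sequence ids
#' as dimnames.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param metric Overrides the metric in the encoder config if given.
#' @return A symmetric numeric matrix of class `dissimilarity_matrix`.
#' @export
dissimilarity_matrix <- function(fm, metric = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  metric <- metric %||% fm$config$metric
  metric <- match.arg(metric, c("euclidean", "manhattan"))
  M <- as.matrix(fm)
  D <- as.matrix(dist(M, method = metric))
  # dist() can leave ~1e-16 asymmetries after as.matrix; symmetrize exactly.
  D <- (D + t(D)) / 2
  diag(D) <- 0
  class(D) <- c("dissimilarity_matrix", class(D))
  D
}
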