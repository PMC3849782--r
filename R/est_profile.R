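#' Classify a group's ESTs as redundant or unique
#'
#' Within a gene group, an EST aligning to two or more positions (counting
#' retained alignment records to genes of that group, whether the same
#' gene or different genes) is *redundant*; an EST with exactly one
#' retained alignment is *unique*. Every EST with at least one hit falls
#' in exactly one of the two sets.
#'
#' @param hits EST-hit tibble (`est_id`, `gene_id`, `group_label`),
#'   already E-value filtered and deduplicated.
#' @param group The group label to profile.
#' @return An object of class `est_group_profile`: list with
#'   `group_label`, `genes_with_hits` (distinct genes hit), `redundant`
#'   and `unique` (character vectors of EST ids).
#' @export
classify_ests <- function(hits, group) {
  h <- dplyr::filter(hits, .data$group_label == group)
  counts <- dplyr::count(h, .data$est_id)
  structure(
    list(
      group_label = group,
      genes_with_hits = dplyr::n_distinct(h$gene_id),
      redundant = sort(counts$est_id[counts$n >= 2]),
      unique = sort(counts$est_id[counts$n == 1])
    ),
    class = "est_group_profile"
  )
}

#' @export
print.est_group_profile <- function(x, ...) {
  cat(sprintf(
    "<est_group_profile> group '%s': %d gene(s) hit, %d redundant, %d unique EST(s)\n",
    x$group_label, x$genes_with_hits, length(x$redundant), length(x$unique)
  ))
  invisible(x)
}

#' Cross-group EST overlap statistics
#'
#' Intersects the redundant and unique EST sets of two group profiles and
#' expresses the common counts as a percentage of the reference group's
#' count (1-decimal reporting). Common counts are symmetric in the two
#' profiles; only the percentage depends on which group is the reference.
#'
#' @param profile_a,profile_b `est_group_profile` objects for disjoint
#'   gene groups.
#' @param reference Which group's counts form the percentage denominator:
#'   the group label, or `"a"`/`"b"` positionally. Default: profile_a.
#' @return A tibble with one row per category (`redundant`, `unique`):
#'   counts for both groups, the common count, and `pct_of_reference`
#'   (`NA` when the reference count is zero).
#' @export
group_overlap_stats <- function(profile_a, profile_b, reference = NULL) {
  stopifnot(
    inherits(profile_a, "est_group_profile"),
    inherits(profile_b, "est_group_profile")
  )
  reference <- reference %||% profile_a$group_label
  ref_is_a <- identical(reference, "a") ||
    identical(reference, profile_a$group_label)
  if (!ref_is_a && !identical(reference, "b") &&
      !identical(reference, profile_b$group_label)) {
    abort(sprintf("Unknown reference group '%s'.", reference))
  }
  one_row <- function(category, set_a, set_b) {
    common <- length(intersect(set_a, set_b))
    ref_n <- if (ref_is_a) length(set_a) else length(set_b)
    tibble(
      category = category,
      n_a = length(set_a),
      n_b = length(set_b),
      common = common,
      pct_of_reference = if (ref_n == 0) {
        NA_real_
      } else {
        round_half_up(100 * common / ref_n, 1)
      }
    )
  }
  out <- dplyr::bind_rows(
    one_row("redundant", profile_a$redundant, profile_b$redundant),
    one_row("unique", profile_a$unique, profile_b$unique)
  )
  names(out)[names(out) == "n_a"] <- paste0("n_", profile_a$group_label)
  names(out)[names(out) == "n_b"] <- paste0("n_", profile_b$group_label)
  attr(out, "reference") <- if (ref_is_a) profile_a$group_label else profile_b$group_label
  out
}

#' Full EST profile table across groups
#'
#' Profiles every group present in the hit table and, when exactly two
#' groups are present, appends their overlap statistics.
#'
#' @param hits EST-hit tibble (`est_id`, `gene_id`, `group_label`).
#' @param reference Reference group label for percentages (default: first
#'   group in label order).
#' @return A list with `profiles` (tibble: `group_label`,
#'   `genes_with_hits`, `total_ests`, `redundant`, `unique`) and `overlap`
#'   (tibble from [group_overlap_stats()], or `NULL` when the number of
#'   groups differs from two).
#' @export
est_profile_table <- function(hits, reference = NULL) {
  groups <- sort(unique(hits$group_label))
  profs <- purrr::map(groups, ~ classify_ests(hits, .x))
  summary <- purrr::map_dfr(profs, function(p) {
    tibble(
      group_label = p$group_label,
      genes_with_hits = p$genes_with_hits,
      total_ests = length(p$redundant) + length(p$unique),
      redundant = length(p$redundant),
      unique = length(p$unique)
    )
  })
  overlap <- NULL
  if (length(profs) == 2) {
    overlap <- group_overlap_stats(
      profs[[1]], profs[[2]],
      reference = reference %||% profs[[1]]$group_label
    )
  }
  list(profiles = summary, overlap = overlap)
}

#' Published EST profile reference counts
#'
#' Loads the packaged redundant/unique/common EST counts per gene group
#' for plant CPP transcription factors, as published for the NCBI dbEST
#' and PlantGDB searches (overall and per species). These are reference
#' counts carried as a fixture; the underlying alignment records are not
#' distributed.
#'
#' @return A tibble with columns `database`, `subset`, `category`,
#'   `group_I`, `group_II`, `common`.
#' @export
est_profile_reference <- function() {
  path <- system.file("extdata", "est_profile_counts.csv",
                      package = "fuzzyfam", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
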