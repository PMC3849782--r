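#' Residue class scheme for composition statistics
#'
#' Defines the disjoint residue classes whose percentages are reported.
#' Defaults: acidic = D, E; basic = K, R, H; hydrophobic = A, V, L, I, M,
#' F, W. Cysteine is deliberately left out of the hydrophobic class: in
#' Cys-rich domains such as CXC (roughly 9 cysteines in ~46 residues)
#' counting C as hydrophobic would inflate the hydrophobic percentage far
#' above the ~20% characteristic of these domains.
#'
#' @param ... Named character vectors of one-letter residue codes, one per
#'   class. Classes must be disjoint and drawn from the 20 standard
#'   letters.
#' @return A named list of class `residue_class_scheme`.
#' @examples
#' residue_class_scheme() # the default three classes
#' @export
residue_class_scheme <- function(...) {
  classes <- list(...)
  if (length(classes) == 0) {
    classes <- list(
      acidic = c("D", "E"),
      basic = c("K", "R", "H"),
      hydrophobic = c("A", "V", "L", "I", "M", "F", "W")
    )
  }
  if (is.null(names(classes)) || any(names(classes) == "")) {
    abort("Every residue class must be named.")
  }
  all_letters <- unlist(classes)
  if (!all(all_letters %in% AA_STANDARD)) {
    abort(sprintf(
      "Non-standard residue letter(s) in scheme: %s",
      paste(setdiff(all_letters, AA_STANDARD), collapse = ", ")
    ))
  }
  if (anyDuplicated(all_letters)) {
    abort(sprintf(
      "Residue classes must be disjoint; duplicated: %s",
      paste(unique(all_letters[duplicated(all_letters)]), collapse = ", ")
    ))
  }
  structure(classes, class = "residue_class_scheme")
}

#' Extract (merged) domain subsequences from proteins
#'
#' Slices each sequence at the coordinates of its domain hits (1-based,
#' inclusive), merging overlapping or bookended intervals, and
#' concatenates the slices in sequence order. Sequences with no matching
#' hit yield an empty subsequence and are flagged.
#'
#' @param records Sequence tibble (`id`, `sequence`).
#' @param hits Domain-hit tibble with non-missing `start`/`end` columns.
#' @param models Optional character vector restricting which
#'   `domain_model` values are used (default: all).
#' @return A tibble with columns `sequence_id`, `subsequence`,
#'   `n_intervals`, `flagged` (TRUE when no hit matched).
#' @export
extract_domain_subsequences <- function(records, hits, models = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (!is.null(models)) {
    hits <- dplyr::filter(hits, .data$domain_model %in% models)
  }
  hits <- dplyr::filter(hits, !is.na(.data$start) & !is.na(.data$end))
  purrr::pmap_dfr(
    list(records$id, records$sequence),
    function(id, seq) {
      h <- hits[hits$sequence_id == id, , drop = FALSE]
      if (nrow(h) == 0) {
        return(tibble(
          sequence_id = id, subsequence = "", n_intervals = 0L, flagged = TRUE
        ))
      }
      if (any(h$end > nchar(seq)) || any(h$start < 1)) {
        abort(sprintf(
          "Domain interval out of range for sequence '%s' (length %d).",
          id, nchar(seq)
        ))
      }
      iv <- merge_intervals(h$start, h$end)
      sub <- paste(substring(seq, iv$start, iv$end), collapse = "")
      tibble(
        sequence_id = id, subsequence = sub,
        n_intervals = nrow(iv), flagged = FALSE
      )
    }
  )
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Residue-class percentages of a subsequence
#'
#' @param subsequence Non-empty amino-acid string (composition only; the
#'   result is invariant to letter order).
#' @param scheme A [residue_class_scheme()].
#' @return A named numeric vector: `100 * class count / length` per class,
#'   unrounded.
#' @examples
#' residue_class_percentages("DEKR") # acidic 50, basic 50, hydrophobic 0
#' @export
residue_class_percentages <- function(subsequence, scheme = residue_class_scheme()) {
  stopifnot(inherits(scheme, "residue_class_scheme"))
  if (!is.character(subsequence) || length(subsequence) != 1 ||
      nchar(subsequence) == 0) {
    abort("`subsequence` must be a single non-empty string.")
  }
  letters_vec <- strsplit(subsequence, "")[[1]]
  L <- length(letters_vec)
  vapply(scheme, function(cls) 100 * sum(letters_vec %in% cls) / L, 0)
}

#' Per-sequence composition table over domain subsequences
#'
#' Convenience wrapper: extracts domain subsequences, computes class
#' percentages per sequence, and attaches group labels.
#'
#' @param records Sequence tibble (`id`, `sequence`).
#' @param hits Domain-hit tibble with coordinates.
#' @param models Optional domain-model filter.
#' @param scheme A [residue_class_scheme()].
#' @param groups Optional tibble (`gene_id` or `id`, `group_label`)
#'   attaching a group to each sequence.
#' @return A tibble with `sequence_id`, `group_label` (NA when no mapping
#'   given) and one percentage column per class; sequences with no
#'   matching domain are dropped with a message.
#' @export
composition_table <- function(records, hits, models = NULL,
                              scheme = residue_class_scheme(),
                              groups = NULL) {
  subs <- extract_domain_subsequences(records, hits, models)
  if (any(subs$flagged)) {
    inform(sprintf(
      "%d sequence(s) have no matching domain hit and are dropped from the composition table.",
      sum(subs$flagged)
    ))
    subs <- subs[!subs$flagged, , drop = FALSE]
  }
  pct <- purrr::map(subs$subsequence, residue_class_percentages, scheme = scheme)
  out <- dplyr::bind_cols(
    tibble(sequence_id = subs$sequence_id),
    dplyr::bind_rows(purrr::map(pct, as.list))
  )
  if (!is.null(groups)) {
    g <- as.data.frame(groups)
    names(g)[names(g) == "id"] <- "gene_id"
    out$group_label <- g$group_label[match(out$sequence_id, g$gene_id)]
  } else {
    out$group_label <- NA_character_
  }
  dplyr::relocate(out, "sequence_id", "group_label")
}

#' Group means of residue-class percentages
#'
#' Unweighted arithmetic means over the sequences of each group, reported
#' to 2 decimals (half-up rounding); the unrounded means are kept in
#' `*_raw` columns.
#'
#' @param rows A tibble with a `group_label` column and one numeric
#'   percentage column per class (e.g. from [composition_table()] or the
#'   packaged reference fixture).
#' @return A tibble with one row per group: `group_label`, `n`, the
#'   rounded class means, and `*_raw` unrounded means.
#' @export
group_composition_means <- function(rows) {
  if (!"group_label" %in% names(rows)) {
    abort("`rows` must have a `group_label` column.")
  }
  if (any(is.na(rows$group_label))) {
    abort("Every row must carry a group label.")
  }
  num_cols <- names(rows)[vapply(rows, is.numeric, TRUE)]
  if (length(num_cols) == 0) {
    abort("No numeric percentage columns found.")
  }
  means <- dplyr::summarise(
    dplyr::group_by(as_tibble(rows), .data$group_label),
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(num_cols), mean),
    .groups = "drop"
  )
  raw <- means[num_cols]
  names(raw) <- paste0(num_cols, "_raw")
  means[num_cols] <- lapply(means[num_cols], round_half_up, digits = 2)
  dplyr::bind_cols(means, raw)
}

#' Published CXC-domain composition reference values
#'
#' Loads the packaged per-gene acidic/basic/hydrophobic percentages of the
#' CXC domains of plant CPP transcription factors, by subfamily group
#' (Arabidopsis, rice and maize genes). These are published reference
#' values carried as a fixture — the original domain subsequences are not
#' distributed, so they cannot be recomputed here.
#'
#' @return A tibble with columns `gene_id`, `group_label`, `acidic`,
#'   `basic`, `hydrophobic`.
#' @export
cxc_composition_reference <- function() {
  path <- system.file("extdata", "cxc_composition_groups.csv",
                      package = "fuzzyfam", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
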