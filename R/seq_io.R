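#' Read protein sequences from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a tibble of
#' sequence records. Sequences are upper-cased on ingest; gap characters
#' (`-` and `.`) are stripped with a warning. The 20 standard amino-acid
#' letters plus the ambiguity letters B, Z, X, U and O are accepted; any
#' other residue character is an error reporting its position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header, unique), `sequence` (upper-case amino acids) and
#'   `description` (remainder of the header, `NA` if absent), one row per
#'   record in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 first", "ACDE", ">p2", "mkvw"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: '%s'", path))
  }
  # BStringSet accepts arbitrary letters so residue validation (with
  # positions) stays in our hands rather than failing opaquely at parse.
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(sprintf("FASTA file '%s' contains no records.", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  if (any(ids == "")) {
    abort("FASTA record with an empty identifier.")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  n_gap <- sum(vapply(gregexpr("[-.]", seqs), function(m) sum(m > 0), 0L))
  if (n_gap > 0) {
    warn(sprintf("Stripped %d gap character(s) ('-'/'.') from sequences.", n_gap))
    seqs <- gsub("[-.]", "", seqs)
  }
  allowed <- paste0(c(AA_STANDARD, AA_AMBIGUOUS, "*"), collapse = "")
  bad <- regexpr(sprintf("[^%s]", allowed), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf(
      "Invalid residue character '%s' in record '%s' at position %d.",
      substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]
    ))
  }
  seqs <- sub("\\*$", "", seqs) # trailing stop codons from translated CDS
  if (any(nchar(seqs) == 0)) {
    abort(sprintf(
      "Record '%s' has an empty sequence.", ids[which(nchar(seqs) == 0)[1]]
    ))
  }
  tibble(id = unname(ids), sequence = unname(seqs), description = unname(desc))
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble with `id` and `sequence` columns (as returned by
#'   [read_fasta()]); an optional `description` column is appended to the
#'   headers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  headers <- records$id
  if ("description" %in% names(records)) {
    has_desc <- !is.na(records$description) & records$description != ""
    headers[has_desc] <- paste(headers[has_desc], records$description[has_desc])
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read domain hits from a TSV or hmmscan domtblout file
#'
#' Reads per-sequence domain-model hits and applies an inclusive E-value
#' cutoff (`e_value <= cutoff`), following the convention that a stated
#' cutoff retains the boundary. The format is auto-detected: files whose
#' first line starts with `#` are parsed as hmmscan `--domtblout` output
#' (per-domain independent E-value, alignment coordinates); otherwise a
#' header TSV with columns `seq_id`, `domain`, `evalue` and optional
#' `start`, `end` is expected.
#'
#' @param path Path to the hits file.
#' @param e_value_cutoff Maximum E-value retained (inclusive). Default 1,
#'   the conventional permissive threshold for Pfam scans feeding
#'   architecture features.
#' @return A tibble with columns `sequence_id`, `domain_model`, `e_value`,
#'   `start`, `end` (coordinates `NA` when absent).
#' @export
read_domain_hits <- function(path, e_value_cutoff = 1) {
  if (!file.exists(path)) {
    abort(sprintf("Domain hits file not found: '%s'", path))
  }
  first <- readLines(path, n = 1L)
  if (length(first) > 0 && startsWith(first, "#")) {
    hits <- parse_domtblout(path)
  } else {
    hits <- parse_domain_tsv(path)
  }
  if (any(hits$e_value < 0)) {
    abort("Negative E-value in domain hits.")
  }
  bad_coord <- !is.na(hits$start) & !is.na(hits$end) & hits$start > hits$end
  if (any(bad_coord)) {
    abort(sprintf(
      "Domain hit with start > end for sequence '%s'.",
      hits$sequence_id[which(bad_coord)[1]]
    ))
  }
  hits <- dplyr::filter(hits, .data$e_value <= e_value_cutoff)
  if (nrow(hits) == 0) {
    warn("No domain hits retained after E-value filtering.")
  }
  hits
}

parse_domain_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  required <- c("seq_id", "domain", "evalue")
  if (!all(required %in% names(df))) {
    abort(sprintf(
      "Domain TSV must have columns %s (got: %s).",
      paste(required, collapse = ", "), paste(names(df), collapse = ", ")
    ))
  }
  ev <- suppressWarnings(as.numeric(df$evalue))
  if (any(is.na(ev) & !is.na(df$evalue))) {
    abort(sprintf(
      "Unparseable E-value at data line %d of '%s'.",
      which(is.na(ev) & !is.na(df$evalue))[1], path
    ))
  }
  tibble(
    sequence_id = as.character(df$seq_id),
    domain_model = as.character(df$domain),
    e_value = ev,
    start = if ("start" %in% names(df)) as.integer(df$start) else NA_integer_,
    end = if ("end" %in% names(df)) as.integer(df$end) else NA_integer_
  )
}

# hmmscan --domtblout: whitespace-separated, comment lines start with '#'.
# Column 1 = target (domain model), 4 = query (sequence), 13 = per-domain
# independent E-value, 18/19 = alignment coordinates on the query.
parse_domtblout <- function(path) {
  lines <- readLines(path)
  keep <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(
      sequence_id = character(), domain_model = character(),
      e_value = double(), start = integer(), end = integer()
    ))
  }
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < 19)) {
    abort(sprintf(
      "Unparseable domtblout row at line %d (fewer than 19 fields).",
      keep[which(n_fields < 19)[1]]
    ))
  }
  ev <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 13L)))
  if (any(is.na(ev))) {
    abort(sprintf(
      "Unparseable E-value in domtblout at line %d.", keep[which(is.na(ev))[1]]
    ))
  }
  tibble(
    sequence_id = vapply(fields, `[`, "", 4L),
    domain_model = vapply(fields, `[`, "", 1L),
    e_value = ev,
    start = as.integer(vapply(fields, `[`, "", 18L)),
    end = as.integer(vapply(fields, `[`, "", 19L))
  )
}

#' Flag hits that reference unknown sequence ids
#'
#' Domain or EST hit tables are ingested independently of the FASTA, so a
#' hit may reference a sequence absent from the collection. Such hits are
#' retained; this helper reports them for inspection.
#'
#' @param hits A hits tibble with a `sequence_id` column.
#' @param records A sequence tibble with an `id` column.
#' @return The rows of `hits` whose `sequence_id` is not in `records$id`.
#' @export
flag_unknown_ids <- function(hits, records) {
  unknown <- dplyr::filter(hits, !(.data$sequence_id %in% records$id))
  if (nrow(unknown) > 0) {
    inform(sprintf(
      "%d hit(s) reference sequence ids absent from the collection: %s",
      nrow(unknown), paste(unique(unknown$sequence_id), collapse = ", ")
    ))
  }
  unknown
}

#' Read EST alignment hits with a gene-to-group mapping
#'
#' Reads EST-to-gene alignment records from BLAST tabular output
#' (`-outfmt 6`: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore; headerless) or a simple header TSV
#' with columns `est_id`, `gene_id`, `evalue`. Hits are retained when
#' `e_value < e_value_cutoff` (strictly below), exactly duplicated rows are
#' dropped, and each hit is labelled with its gene's group.
#'
#' @param path Path to the hit table.
#' @param gene_groups Either a two-column TSV path or a data frame mapping
#'   `gene_id` to `group_label`.
#' @param e_value_cutoff Strict upper bound on retained E-values. Default
#'   `1e-5`.
#' @return A tibble with columns `est_id`, `gene_id`, `group_label`,
#'   `e_value` (plus `identity`, `est_start`, `est_end`, `gene_start`,
#'   `gene_end` for BLAST input).
#' @export
read_est_hits <- function(path, gene_groups, e_value_cutoff = 1e-5) {
  if (!file.exists(path)) {
    abort(sprintf("EST hits file not found: '%s'", path))
  }
  mapping <- read_gene_groups(gene_groups)
  first <- readLines(path, n = 1L)
  is_blast6 <- length(first) == 1 &&
    length(strsplit(first, "\t")[[1]]) >= 12 &&
    !grepl("est_id", tolower(first), fixed = TRUE)
  if (is_blast6) {
    df <- readr::read_tsv(
      path,
      col_names = c(
        "est_id", "gene_id", "identity", "aln_length", "mismatch", "gapopen",
        "est_start", "est_end", "gene_start", "gene_end", "e_value", "bitscore"
      ),
      show_col_types = FALSE, progress = FALSE
    )
    hits <- dplyr::select(
      df, "est_id", "gene_id", "e_value", "identity",
      "est_start", "est_end", "gene_start", "gene_end"
    )
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    names(df) <- tolower(names(df))
    required <- c("est_id", "gene_id", "evalue")
    if (!all(required %in% names(df))) {
      abort(sprintf(
        "EST TSV must have columns %s.", paste(required, collapse = ", ")
      ))
    }
    hits <- tibble(
      est_id = as.character(df$est_id),
      gene_id = as.character(df$gene_id),
      e_value = as.numeric(df$evalue)
    )
  }
  if (any(is.na(hits$e_value))) {
    abort("Unparseable E-value in EST hits.")
  }
  if (any(hits$e_value < 0)) {
    abort("Negative E-value in EST hits.")
  }
  n0 <- nrow(hits)
  hits <- dplyr::distinct(hits)
  if (nrow(hits) < n0) {
    inform(sprintf("Dropped %d exactly duplicated EST hit row(s).", n0 - nrow(hits)))
  }
  hits <- dplyr::filter(hits, .data$e_value < e_value_cutoff)
  missing <- setdiff(unique(hits$gene_id), mapping$gene_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Gene id(s) missing from the group mapping: %s",
      paste(missing, collapse = ", ")
    ))
  }
  dplyr::relocate(
    dplyr::left_join(hits, mapping, by = "gene_id"),
    "est_id", "gene_id", "group_label", "e_value"
  )
}

read_gene_groups <- function(gene_groups) {
  if (is.character(gene_groups) && length(gene_groups) == 1) {
    df <- readr::read_tsv(gene_groups, show_col_types = FALSE, progress = FALSE)
  } else {
    df <- as.data.frame(gene_groups)
  }
  names(df) <- tolower(names(df))
  if (!all(c("gene_id", "group_label") %in% names(df))) {
    if (ncol(df) >= 2) {
      names(df)[1:2] <- c("gene_id", "group_label")
    } else {
      abort("Gene-group mapping needs columns gene_id and group_label.")
    }
  }
  tibble(
    gene_id = as.character(df$gene_id),
    group_label = as.character(df$group_label)
  )
}
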