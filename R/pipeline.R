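#' Validate a run configuration
#'
#' Reads a YAML (or JSON) run configuration, fills documented defaults,
#' and checks every constraint, reporting *all* violations at once rather
#' than failing on the first. Recognized fields:
#'
#' * `fasta` (required): path to the protein FASTA.
#' * `domains`: path to a domain-hit table; `domain_evalue` (default 1).
#' * `encoder`: `peptide_lengths`, `peptide_weight_base`, `domain_weight`,
#'   `metric`, `ambiguity_policy` (defaults as in [encoder_config()]).
#' * `cluster`: fixed `k` and `r` — or `sweep`: `k_grid`, `r_grid`,
#'   `select_rule`.
#' * `n_restarts` (default 5), `seed` (default 1), `output_dir`
#'   (default `"fuzzyfam_out"`).
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return A validated list of class `run_config` with defaults filled in.
#'   On any violation an error of class `fuzzyfam_config_error` is thrown
#'   whose message enumerates every problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: '%s'", config),
            class = "fuzzyfam_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("Config must be a file path or a named list.",
          class = "fuzzyfam_config_error")
  }
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (is.null(config$fasta)) {
    note("`fasta` is required.")
  } else if (!file.exists(config$fasta)) {
    note(sprintf("FASTA file does not exist: '%s'", config$fasta))
  }
  if (!is.null(config$domains) && !file.exists(config$domains)) {
    note(sprintf("Domain hits file does not exist: '%s'", config$domains))
  }
  config$domain_evalue <- config$domain_evalue %||% 1
  if (config$domain_evalue < 0) {
    note("`domain_evalue` must be non-negative.")
  }
  enc <- config$encoder %||% list()
  enc$peptide_lengths <- enc$peptide_lengths %||% 1:4
  enc$peptide_weight_base <- enc$peptide_weight_base %||% 10
  enc$domain_weight <- enc$domain_weight %||% 100
  enc$metric <- enc$metric %||% "euclidean"
  enc$ambiguity_policy <- enc$ambiguity_policy %||% "skip"
  encoder <- tryCatch(
    encoder_config(
      peptide_lengths = enc$peptide_lengths,
      peptide_weight_base = enc$peptide_weight_base,
      domain_weight = enc$domain_weight,
      ambiguity_policy = enc$ambiguity_policy,
      metric = enc$metric
    ),
    error = function(e) {
      note(paste("encoder:", conditionMessage(e)))
      NULL
    }
  )
  has_cluster <- !is.null(config$cluster)
  has_sweep <- !is.null(config$sweep)
  if (has_cluster && has_sweep) {
    note("Specify either `cluster` (fixed k, r) or `sweep`, not both.")
  }
  if (!has_cluster && !has_sweep) {
    config$sweep <- list() # default: sweep with default grids
    has_sweep <- TRUE
  }
  if (has_cluster) {
    if (is.null(config$cluster$k) || config$cluster$k < 2) {
      note("`cluster.k` must be an integer >= 2.")
    }
    r <- config$cluster$r %||% 2
    if (r <= 1) {
      note("Membership exponent must exceed 1 (`cluster.r`).")
    }
    config$cluster$r <- r
  }
  if (has_sweep) {
    config$sweep$k_grid <- config$sweep$k_grid %||% 2:4
    config$sweep$r_grid <- config$sweep$r_grid %||%
      c(1.5, 2, 2.5, 5, 7.5, 8, 8.1, 8.2, 8.5, 9, 10)
    config$sweep$select_rule <- config$sweep$select_rule %||% "mean"
    if (any(config$sweep$k_grid < 2)) {
      note("`sweep.k_grid` values must be >= 2.")
    }
    if (any(config$sweep$r_grid <= 1)) {
      note("Membership exponents in `sweep.r_grid` must exceed 1.")
    }
    if (!config$sweep$select_rule %in% c("mean", "minmax")) {
      note("`sweep.select_rule` must be 'mean' or 'minmax'.")
    }
  }
  config$n_restarts <- config$n_restarts %||% 5
  config$seed <- config$seed %||% 1
  config$output_dir <- config$output_dir %||% "fuzzyfam_out"
  # k-grid / k feasibility against the actual record count, when readable
  if (length(problems) == 0) {
    n <- nrow(read_fasta(config$fasta))
    kmax <- if (has_cluster) config$cluster$k else max(config$sweep$k_grid)
    if (kmax >= n) {
      note(sprintf(
        "Largest requested k (%d) must be below the number of sequences (%d).",
        kmax, n
      ))
    }
  }
  if (length(problems) > 0) {
    abort(
      paste0(
        "Invalid run configuration:\n",
        paste0("  - ", problems, collapse = "\n")
      ),
      class = "fuzzyfam_config_error"
    )
  }
  config$encoder_config <- encoder
  structure(config, class = "run_config")
}

#' Run the full subclassification pipeline
#'
#' Executes encode -> dissimilarity -> cluster (fixed k, r) or sweep ->
#' harden -> report. All intermediate artifacts are written under the
#' configured output directory: the dissimilarity matrix (square CSV with
#' id header row/column), the membership matrix (CSV, id column plus one
#' column per cluster), hard labels (TSV), the sweep table (TSV, sweep
#' mode only) and the run report (JSON). All randomness flows from the
#' single top-level seed through per-stage derived seeds, so two runs of
#' the same config are byte-identical.
#'
#' @param config A `run_config` from [validate_config()] (a path or list
#'   is validated first).
#' @return An object of class `run_report`: list with `selected` (k, r),
#'   `group_sizes`, `n`, `paths` to artifacts, `config` echo, `version`
#'   and `wall_clock_s`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    config <- validate_config(config)
  }
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  records <- stage("read_fasta", read_fasta(config$fasta))
  hits <- NULL
  if (!is.null(config$domains)) {
    hits <- stage(
      "read_domain_hits",
      read_domain_hits(config$domains, e_value_cutoff = config$domain_evalue)
    )
  }
  fm <- stage(
    "encode",
    build_feature_matrix(records, hits, config$encoder_config)
  )
  D <- stage("dissimilarity", dissimilarity_matrix(fm))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    dissimilarity = file.path(config$output_dir, "dissimilarity.csv"),
    membership = file.path(config$output_dir, "membership.csv"),
    labels = file.path(config$output_dir, "labels.tsv"),
    report = file.path(config$output_dir, "report.json")
  )
  utils::write.csv(as.data.frame(unclass(D)), paths$dissimilarity)

  sweep_obj <- NULL
  if (!is.null(config$cluster)) {
    fit <- stage("cluster", fanny_fit(
      D, k = config$cluster$k, r = config$cluster$r,
      n_restarts = config$n_restarts, seed = derive_seed(config$seed, 1)
    ))
    selected <- list(k = config$cluster$k, r = config$cluster$r)
  } else {
    sweep_obj <- stage("sweep", sweep_parameters(
      D, k_grid = config$sweep$k_grid, r_grid = config$sweep$r_grid,
      select_rule = config$sweep$select_rule,
      n_restarts = config$n_restarts, seed = derive_seed(config$seed, 2)
    ))
    if (is.null(sweep_obj$selected)) {
      abort("Pipeline stage 'sweep' failed: all grid cells degenerate.")
    }
    selected <- list(k = sweep_obj$selected$k, r = sweep_obj$selected$r)
    fit <- sweep_obj$fits[[sprintf("k=%d,r=%g", selected$k, selected$r)]]
    paths$sweep_table <- file.path(config$output_dir, "sweep.tsv")
    readr::write_tsv(sweep_obj$table, paths$sweep_table)
  }
  memb <- as.data.frame(fit$membership)
  names(memb) <- sprintf("cluster_%d", seq_len(ncol(memb)))
  readr::write_csv(
    dplyr::bind_cols(tibble(id = rownames(fit$membership)), memb),
    paths$membership
  )
  readr::write_tsv(fit$hard_labels, paths$labels)
  group_sizes <- as.integer(table(
    factor(fit$hard_labels$cluster, levels = seq_len(selected$k))
  ))
  report <- structure(
    list(
      selected = selected,
      group_sizes = group_sizes,
      n = nrow(records),
      objective = fit$objective,
      converged = fit$converged,
      paths = paths,
      config = unclass(config)[setdiff(names(config), "encoder_config")],
      version = as.character(packageVersion("fuzzyfam")),
      wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "run_report"
  )
  jsonlite::write_json(
    unclass(report)[setdiff(names(report), "wall_clock_s")],
    paths$report,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> n = %d | selected k = %d, r = %g | group sizes: %s\n",
    x$n, x$selected$k, x$selected$r, paste(x$group_sizes, collapse = ", ")
  ))
  cat("artifacts:", paste(unlist(x$paths), collapse = ", "), "\n")
  invisible(x)
}
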