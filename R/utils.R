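# Internal helpers shared across modules.

# The 20 standard amino-acid one-letter codes, alphabetical.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Ambiguity / non-standard letters accepted on ingest but excluded from
# k-mer counting by the default policy.
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O")

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are unaffected. A `NULL`
#' seed runs the code against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific seed from a top-level seed, kept within the 32-bit
# integer range so set.seed() accepts it on every platform.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

# Round half away from zero to `digits` decimals (display convention for
# composition percentages; base round() uses round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate a square symmetric dissimilarity matrix, returning it with ids.
check_dissimilarity <- function(D, arg = "D") {
  if (inherits(D, "dist")) {
    D <- as.matrix(D)
  }
  if (!is.matrix(D) || !is.numeric(D)) {
    abort(sprintf("`%s` must be a numeric matrix or a 'dist' object.", arg))
  }
  if (nrow(D) != ncol(D)) {
    abort(sprintf("`%s` must be square.", arg))
  }
  if (any(!is.finite(D))) {
    abort(sprintf("`%s` contains non-finite entries.", arg))
  }
  if (any(D < 0)) {
    abort(sprintf("`%s` contains negative dissimilarities.", arg))
  }
  if (max(abs(D - t(D))) > 1e-12) {
    abort(sprintf("`%s` is not symmetric (tolerance 1e-12).", arg))
  }
  if (any(abs(diag(D)) > 1e-12)) {
    abort(sprintf("`%s` must have a zero diagonal.", arg))
  }
  if (is.null(rownames(D))) {
    ids <- as.character(seq_len(nrow(D)))
    dimnames(D) <- list(ids, ids)
  }
  D
}
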