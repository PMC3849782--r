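# Shared in-code fixtures for the test suite.

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_temp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, path)
  path
}

# Random points in the plane with Euclidean dissimilarities — instances on
# which the alternating minimizer's descent guarantee holds exactly.
random_euclidean_instance <- function(n, dims = 2, scale = 10) {
  pts <- matrix(runif(n * dims, 0, scale), n)
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("p", seq_len(n))
  D
}

# Two tight pairs far apart: the canonical well-separated k = 2 instance.
two_pair_dissimilarity <- function(gap = 10, jitter = 0.1) {
  x <- c(0, jitter, gap, gap + jitter)
  D <- as.matrix(dist(x))
  rownames(D) <- colnames(D) <- paste0("p", 1:4)
  D
}

# Block dissimilarity: within-cluster d = `within`, between = `between`.
block_dissimilarity <- function(sizes, within, between) {
  lab <- rep(seq_along(sizes), sizes)
  n <- length(lab)
  D <- matrix(between, n, n)
  same <- outer(lab, lab, "==")
  D[same] <- within
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("p", seq_len(n))
  list(D = D, labels = lab)
}
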