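Package: fuzzyfam
Title: Fuzzy Subclassification of Protein Families from k-mer and Domain
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Subclassifies protein families (such as the plant CPP
    transcription factors carrying cysteine-rich CXC domains) by encoding
    each protein as weighted, normalized k-mer frequencies (k = 1..4)
    concatenated with weighted Pfam-style domain counts, clustering the
    resulting dissimilarity matrix with a FANNY-type fuzzy algorithm under
    an arbitrary membership exponent, and selecting the cluster number and
    fuzziness by silhouette width. Also provides EST expression-profile
    summaries (redundant/unique transcript counting and cross-group
    overlap), domain-subsequence residue-class composition statistics, and
    a seeded synthetic-family generator with planted subfamily structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
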