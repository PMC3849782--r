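---
title: "Methods: fuzzy subfamily clustering from k-mer and domain features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy subfamily clustering from k-mer and domain features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyfam)
```

## The problem

Protein families defined by a shared domain — such as the plant CPP
transcription factors, which all carry cysteine-rich CXC DNA-binding
domains — frequently contain functionally distinct subfamilies. Multiple
alignment plus tree building becomes awkward for such sets: members differ
greatly in length, the conserved domains cover a small fraction of each
sequence, and subfamily boundaries are gradual rather than sharp. `fuzzyfam`
takes an alignment-free route: it embeds every protein in a common feature
space built from short-peptide content and domain architecture, clusters
the resulting dissimilarity matrix with a fuzzy algorithm that lets a
protein belong partially to several clusters, and selects the number of
clusters and the degree of fuzziness by silhouette width.

## The feature encoding

For each peptide length $n \in \{1,2,3,4\}$, every overlapping window of
length $n$ is counted. Writing $f_i$ for the count of peptide $i$ and
$\sum_j f_j$ for the total count of same-length windows in that protein,
the feature value is

$$A_i = w \frac{f_i}{\sum_j f_j}, \qquad w = 10^n .$$

Two properties matter:

* **Per-block mass.** A non-empty block sums to exactly $10^n$, so the
  tetra-peptide block carries $1000\times$ the mass of the mono-peptide
  block. Specific (long) peptides dominate pairwise distances, while
  composition (short) peptides act as a tie-breaker. The block-sum identity
  is property-tested to $10^{-9}$ over random sequences.
* **Per-sequence normalization.** The denominator is the window total of
  the *same protein* — not a corpus total — so a protein's encoding never
  changes when other records are added or reordered.

Domain architecture enters as a separate block: each domain model hitting
the sequence (after E-value filtering, default $E \le 1$, boundary
inclusive) contributes $100 \times \text{count}$. Counts, not presence:
a protein with two CXC copies differs from one with a single copy, which
is exactly the kind of signal that separates CPP-like subfamilies.

Nominally the k-mer space has $\sum_n 20^n = 168{,}420$ coordinates; real
proteins populate well under 1% of them, so vectors are stored sparsely
(long tibbles) and embedded into the union space on demand.

Choices the encoding leaves open, and what this package does:

* **Ambiguity letters** (B, Z, X, U, O) are accepted on ingest; windows
  containing one are skipped from numerator *and* denominator, so the
  normalization covers the same event space as the counts. A strict
  `"error"` policy is available.
* **Dissimilarity metric.** Nothing in the objective dictates one. The
  default is Euclidean distance on the embedded coordinates — the
  conventional default for dissimilarity-based clustering front-ends —
  with Manhattan as an option. Euclidean also guarantees the descent
  property of the fitting algorithm (below).

## The fuzzy clustering objective

Given the $n \times n$ dissimilarity matrix $D = (d(i,j))$, a cluster
count $k$ and a membership exponent $r > 1$, the algorithm minimizes over
row-stochastic membership matrices $U = (u_{iv})$

$$\min_U \; \sum_{v=1}^{k}
  \frac{\sum_{i}\sum_{j} u_{iv}^r \, u_{jv}^r \, d(i,j)^2}
       {\sum_{j} u_{jv}^r},$$

the FANNY-style dissimilarity-based objective. Note the denominator is
$\sum_j u_{jv}^r$, *without* the conventional factor 2; the package
evaluates the formula exactly as stated, which scales the reported
objective by 2 relative to the Kaufman–Rousseeuw convention but leaves
minimizers (and therefore memberships, labels and silhouettes) unchanged.

### Fitting algorithm

No update rule is canonical for this objective at arbitrary $r$, so the
package uses a relational fuzzy c-means alternation, chosen because it has
a clean descent guarantee:

1. From the current $U$, form cluster weights
   $p_v = u_v^r / \sum_j u_{jv}^r$ and implicit-centroid squared distances
   $a_{iv} = (D^2 p_v)_i - \tfrac12 p_v^\top D^2 p_v$. When $D$ is the
   Euclidean distance matrix of points $x_i$, $a_{iv}$ equals
   $\lVert x_i - c_v\rVert^2$ for the weighted centroid $c_v$ — without
   ever forming coordinates.
2. Update each row by the closed-form simplex minimizer
   $u_{iv} \propto a_{iv}^{-1/(r-1)}$; a row with some $a_{iv} = 0$ puts
   all mass on the zero-distance cluster(s).

Each sweep is one block of an exact alternating minimization of the
centroid-form objective, so for Euclidean-embeddable dissimilarities the
objective sequence is non-increasing; this is asserted (slack $10^{-12}$)
in every fitted run. For general symmetric input, negative $a_{iv}$ from
non-embeddable geometry are clamped at zero.

Correctness is arbitrated by an independent oracle, `brute_force_min()`:
exhaustive evaluation on a per-object simplex grid followed by BFGS polish
in softmax coordinates, from the grid optimum, the uniform matrix and
random starts. On random Euclidean instances with $n \le 6$ and
$r \in \{1.5, 2, 8.2\}$ the fitted objective matches the oracle within
$10^{-4}$ relative (observed gaps are below $10^{-8}$; occasionally the
fitter's polish-free optimum is marginally *better* than the oracle's).

### Numerical choices

* **Initialization**: flat-Dirichlet membership rows, 5 seeded restarts,
  best objective kept. A deterministic farthest-point (`spread_medoids`)
  start is available for reproducibility-sensitive runs; restarts beyond
  the first always randomize.
* **Convergence**: relative objective change below `tol` ($10^{-9}$
  default) or `max_iter` (500); hitting the cap flags `converged = FALSE`
  rather than erroring.
* **Degenerate clusters**: a restart whose membership column loses all
  support (column maximum $< 10^{-6}$) is rerun from a fresh derived seed
  and the event reported. The test is on memberships, not on $u^r$, whose
  column sums underflow at large $r$ even for healthy clusters; for the
  same reason the weights $p_v$ are computed from column-max-rescaled
  powers.
* **Determinism**: all randomness is drawn under a caller-supplied seed
  inside a sandbox that restores the global RNG state, so identical seeds
  give bit-identical fits and callers' random streams are untouched.
* **Supported exponent range.** Beyond $r \approx 20$ the objective of
  well-separated data underflows toward zero (values near $10^{-15}$ on
  toy instances) and its landscape becomes flat below double-precision
  resolution; both the fitter and the brute-force oracle then stall in
  near-hard configurations instead of approaching the theoretical uniform
  $1/k$ limit. The package targets the practically used range — the
  canonical selection grid tops out at $r = 10$ — and the fuzzification
  monotonicity property (memberships strictly closer to uniform at larger
  $r$) is verified at $r = 2$ versus $10$, where fitter and oracle agree
  to $10^{-3}$.

### Hardening

`harden()` assigns each object to its maximum-membership cluster, breaking
ties toward the lowest cluster index, and flags *straddlers* — objects
whose maximum membership is below $1/k + 0.05$, i.e. barely above the
uniform level. An empty straddler set is the fuzzy analogue of "the groups
share no common member".

## Silhouette and model selection

The per-object silhouette is
$s_i = (b_i - a_i)/\max(a_i, b_i)$, with $a_i$ the mean dissimilarity to
the other members of $i$'s cluster and $b_i$ the smallest mean
dissimilarity to another cluster. Some statements of this statistic read
as if $a_i$ and $b_i$ were cluster-level averages; the formula itself is
the standard per-object definition (Rousseeuw's), which this package
implements, reporting per-cluster means alongside — that reconciles both
readings. Conventions: members of singleton clusters score $s_i = 0$, as
do objects with $\max(a_i, b_i) = 0$; a single-cluster partition is an
error. Agreement with the independent `cluster::silhouette()`
implementation is tested to $10^{-9}$ on random instances.

`sweep_parameters()` fits every cell of a $(k, r)$ grid — defaults
$k \in \{2,3,4\}$ and the canonical exponent grid
$r \in \{1.5, 2, 2.5, 5, 7.5, 8, 8.1, 8.2, 8.5, 9, 10\}$ — and scores the
*hardened* partition (fuzzy memberships have no standard silhouette).
Because the selection target ("maximal silhouette for each cluster") can
be read per-cluster or overall, both rules are provided: `"mean"`
(default) maximizes the unweighted mean of $s_i$ over objects, `"minmax"`
maximizes the worst per-cluster mean. Ties break toward smaller $k$, then
smaller $r$. Cells with $k \ge n$ are skipped with a warning; if every
cell is degenerate (e.g. an all-zero dissimilarity matrix) the sweep
returns its table flagged, with no selection.

## EST profiles and domain composition

Two statistics support biological validation of a split:

* **EST profiles.** Within a gene group, an EST whose retained alignments
  (strict $E < 10^{-5}$ by default; deduplicated rows) hit two or more
  positions — same or different genes — is *redundant*; exactly one,
  *unique*. The ≥ 2-records reading imposes no minimum separation between
  positions, which the data formats could not support anyway. Cross-group
  overlap intersects these sets by EST id; the percentage is taken over an
  explicit reference group's count (an EST unique within each of two
  groups can still be a common unique EST). The default EST cutoff follows
  the threshold under which the published group counts were reported; a
  stricter $10^{-10}$ is appropriate for genome-scale screens and is a
  parameter, not a constant.
* **Domain composition.** Domain subsequences are sliced at hit
  coordinates (1-based inclusive, overlaps merged), concatenated, and
  scored as residue-class percentages: $100 \times$ class count / length.
  Default classes — acidic $\{D, E\}$, basic $\{K, R, H\}$, hydrophobic
  $\{A, V, L, I, M, F, W\}$ — are configurable and must be disjoint.
  Cysteine is deliberately excluded from the hydrophobic class: CXC-like
  domains carry roughly 9 cysteines in ~46 residues, and counting C as
  hydrophobic would push hydrophobic percentages far above the ~20%
  characteristic of published reference values for these domains. Display
  rounding is half-up to 2 decimals (group means to the same convention);
  raw values are retained. The packaged per-gene reference table cannot be
  re-derived here — the original domain subsequences are not distributed —
  so it is carried as data and its group means are recomputed from it.

## The synthetic-family generator

`family_spec()` defaults *are* the reference conditions used throughout
the tests: 2 families × 20 members, ancestor lengths 300–500 residues,
between-family per-site divergence 0.5, within-family substitution rate
0.05, and per-family architectures sharing a two-copy "CXC" model plus one
family-specific model. Members are per-site substituted copies of their
family ancestor (substitution always changes the letter, so the rate is
the expected divergence). Amino acids are sampled uniformly by default —
no claim of biological realism; a frequency table can be supplied. Signal
travels through both channels the encoder uses — k-mer content and domain
architecture — and either can be disabled to probe its separate
contribution.

What the generator does *not* emulate: indels and length variation within
a family, positional conservation structure (real CXC domains are
position-specifically conserved), biased amino-acid composition, and
domain-position effects (the encoder is count-based, so N- versus
C-terminal placement is invisible anyway). Passing recovery tests
therefore show that the pipeline separates families whose signal is
k-mer- and architecture-shaped — the regime the method was designed for —
not that it handles alignment-level phenomena like repeat expansions.

`generate_est_table()` plants redundant/unique compositions and
cross-group sharing exactly and returns its own bookkeeping, so profile
counting is verified by round-trip rather than by a second
implementation.

## Problem sizes and runtime envelope

The test suite and the reproduction script run at deliberately desk-scale
sizes: planted recovery over 20 seeds at 2 × 20 sequences; oracle
equivalence on 21 random instances with $n \le 6$ (the brute-force grid is
exhaustive, so instance size is the binding constraint); silhouette
cross-checks on 50 instances up to $n = 50$; the block-sum property over
1000 random sequences. A full sweep (3 cluster counts × 11 exponents, 5
restarts each) on 40 sequences takes a few seconds on one core.

## Known limitations

* The clustering operates on a dense $n \times n$ dissimilarity matrix;
  beyond a few thousand sequences memory and the $O(n^2)$ updates begin to
  bind.
* Membership exponents far above the canonical grid (roughly $r > 20$)
  are outside the numerically supported range, as described above.
* The reported objective follows the stated formula (no factor 2); compare
  against other FANNY implementations up to that constant.
* Domain-count features are position-blind by design; families
  distinguished mainly by domain placement need the composition module or
  external tools.
* EST redundancy counts records, not genomic positions; two retained
  alignments of one EST to the same position (e.g. from overlapping query
  fragments) would count as redundant.
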