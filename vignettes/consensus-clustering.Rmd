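---
title: "Consensus clustering of fingerprints: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering of fingerprints: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consenchem)
```

## The problem and the model

Clustering is used in compound selection to pick representative molecules:
under the similar-property principle, a good partition concentrates each
biological activity class in a few clusters and keeps inactives out of
them. No single algorithm is reliably best, which motivates *consensus
clustering*: run several base clusterers, then merge their partitions.

`consenchem` implements the full stack on binary fingerprint matrices
(molecules × bits, entries 0/1). An **ensemble** at one grid cell
(distance, k) holds six partitions of the same molecules — single,
complete, average and weighted-average (WPGMA) linkage, Ward, and k-means —
all built from the same distance measure and cut to the same requested
cluster count.

### Cumulative voting (CVAA)

A partition of n molecules into k clusters is an n × k membership matrix
**U** with unit row sums. The Ward member is fixed as the reference **U**⁰
(its cluster count becomes the consensus k; it is never re-estimated).
Members are folded in sequentially: vote weights
**W**ⁱ = (**U**ⁱᵀ**U**ⁱ)⁻¹**U**ⁱᵀ**U**⁰ re-express member i's clusters in
the reference labelling, the relabelled votes are **V**ⁱ = **U**ⁱ**W**ⁱ,
and the running average becomes
**U**⁰ ← ((i−1)/i)·**U**⁰ + (1/i)·**V**ⁱ. Since each **U**ⁱ is hard,
**U**ⁱᵀ**U**ⁱ is diagonal with the cluster sizes, and row l of **W**ⁱ is
simply the mean current-consensus row over the molecules of cluster l —
the implementation uses this counting form, with the explicit inversion
kept only as a test oracle. Three readings were genuinely open and are
resolved as follows:

* the loop runs over **all** b members, including the Ward reference
  itself (its first pass is a no-op, **W** = **I**); excluding it is
  available via `include_reference = FALSE`;
* weights are computed against the *current*, progressively soft
  consensus, not against the original hard reference — only the reference
  *choice* is fixed;
* when the grid runs a non-Euclidean distance, "the Ward member" is the
  Ward-linkage partition of *that* ensemble, so every grid cell is
  self-contained.

The soft consensus is hardened by row-wise argmax, ties to the lowest
column index, empty columns dropped with re-indexing. The hardening rule is
an implementation decision; any rule that preserves argmax behaviour on
non-degenerate rows would give the same partitions in the tested settings.

### Graph-based consensus (CSPA, HGPA)

CSPA builds the co-association matrix S — the fraction of members placing
each pair in the same cluster, computed in integer counts and divided by
the member count r once, so entries are exact multiples of 1/r — and
re-cuts it as a weighted graph. HGPA turns every cluster of every member
into a unit-weight hyperedge and cuts the hypergraph directly.

Both consensus functions are defined against a *partitioner contract*
rather than a specific external binary: parts non-empty, largest part at
most ceiling(n/k)·(1 + `balance_slack`), objective the inter-part
similarity weight (CSPA) or the number of cut hyperedges (HGPA). The
shipped defaults are pure R:

* **CSPA**: recursive spectral bisection (Fiedler vector of the graph
  Laplacian, deterministic sign convention, index tie-breaks) followed by
  Kernighan–Lin-style pair swaps that preserve side sizes. Disconnected
  graphs are handled by pre-assigning whole components, which makes
  block-diagonal inputs (perfectly agreeing ensembles) exact zero-cut
  solutions.
* **HGPA**: greedy Fiduccia–Mattheyses-flavoured single-vertex moves under
  the balance cap, restarted from multiple initial assignments and keeping
  the best cut. The start set contains both seeded random balanced
  assignments and *data-derived* starts — each ensemble member's own
  partition repaired to k balanced parts. The data-derived starts matter:
  from a purely random balanced start at large n, every hyperedge already
  spans all parts and no single move can improve the cut, so the descent
  has no gradient to follow.

External partitioners can be plugged in through the `partitioner`
arguments. `balance_slack` defaults to 0.25; this is an engineering choice
(the balance tolerances of the graph-partitioning tools this contract
abstracts are not standardised), and both tests and the acceptance checks
treat it as part of the contract, not a tunable.

### Evaluation

Per activity class, each cluster scores precision a/n, recall a/A and
F = 2PR/(P+R) (F = 0 when a = 0 resolves the 0/0 form); the partition's
F-measure is the maximum cluster F. QPI = p/(p+q+r+s) uses the
active-cluster rule: a non-singleton cluster is *active* when its
focal-class fraction **strictly** exceeds the dataset-wide fraction A/n;
equality leaves a cluster inactive. The dataset-wide fraction is computed
per focal class (one-vs-rest, repeated over classes and macro-averaged),
the only reading consistent with averaging over activity classes. Scores
are reported ×100 to match the conventional percent-scale tables.
Singleton inactive clusters contribute to none of p, q, r, s; the
conservation law p + r + s = A holds identically and is asserted on every
random fixture.

Method comparisons use the classical paired t-test over the cluster-count
grid (df = pairs − 1, two-tailed p, 95% CI). Each method enters as its
**best distance row** — the single row with the highest mean score across
the k grid, the row a benchmark table would bold. The alternative
(independent per-column maxima) is available as `selection = "per_k_max"`
but does not correspond to how published comparison tables of this kind
are built; on the shipped MDDR grid only the best-row convention
reproduces the published t-test statistics. Zero-variance differences
yield a degenerate-flagged result instead of an error.

## The synthetic generator

`generate_planted_dataset()` plants one random prototype fingerprint per
activity class — exactly round(density · m) one-bits at random positions —
and emits members as independent per-bit corruptions at the class flip
probability. Fixed-weight prototypes (rather than i.i.d. Bernoulli bits)
remove prototype-weight variance from the diversity dial; the dial then
has a closed form: the expected within-class Tanimoto is approximately

d(1−f)² + (1−d)f²  over  d(1−f²) + (1−d)(2f−f²),

with d the prototype density and f the flip probability (ratio of per-bit
expectations; tight at fingerprint lengths of a few hundred bits and up).
This expectation is *not* monotone in f over [0, 0.5): once noise
dominates the prototype signal, two members resemble independent random
vectors and their similarity creeps back toward p/(2−p). The useful dial
is the low-noise decreasing branch, and `calibrate_flip_prob()` inverts
the expectation there only, refusing targets below the reachable floor for
the given density. Covering the realistic diversity range of activity
classes (within-class mean Tanimoto ≈ 0.29 for homogeneous classes down to
≈ 0.11 for diverse ones, at 1024 bits) therefore requires varying the
density as well: ≈ 0.11 is unreachable at density 0.05 (floor ≈ 0.18) and
is produced at density 10/1024 with f ≈ 0.05.

What the generator does *not* emulate: real ECFP bit semantics (correlated
substructure bits, heavy-tailed bit frequencies), unequal class overlap,
and background molecules outside any class. Perfect recovery results on
planted data therefore demonstrate the correctness of the pipeline, not
expected performance on real compound collections, where scores in the
tens of percent are typical.

`min_separation` optionally enforces a minimum pairwise Hamming distance
between prototypes (resampling violators), used by the recovery fixtures:
with flip probability f the expected within-class Hamming distance is
2f(1−f)m, and prototypes an order of magnitude further apart make every
base clusterer recover the planted partition exactly.

## Numerical and determinism choices

* Cluster labels are 1-based everywhere; partitions are re-indexed so all
  labels 1..k are occupied after any cut.
* Agglomeration is delegated to `stats::hclust` (`weighted` = "mcquitty",
  `ward` = "ward.D", i.e. the Lance–Williams update applied to the supplied
  distances as-is). Ward crossed with non-Euclidean distances is permitted
  — the experimental grid requires it — with a once-per-session warning,
  since Ward's variance interpretation only holds for Euclidean input.
  Merge tie-breaking is `hclust`'s deterministic behaviour; invariance
  tests use tie-free fixtures.
* k-means initialisation is a seeded maximin sweep (first centroid drawn
  with the seed, each next the row farthest from those chosen, ties to the
  lowest index). A purely uniform draw of k rows would fail to place one
  seed per group on planted data with realistic class sizes, making
  recovery a coin flip rather than a property. Centroid updates follow
  each metric's minimiser (mean / median / bitwise majority with ties set
  to 1); a cluster emptied during iteration is re-seeded with the point
  farthest from its own centroid; the iteration cap is 300.
* Every stochastic component (generator, k-means, HGPA starts) takes an
  explicit integer seed; the pipeline derives per-cell seeds from the
  master seed with fixed prime multipliers, so whole experiment runs are
  byte-reproducible.
* Degenerate inputs fail loudly and early: non-binary fingerprint cells,
  duplicate ids, constant rows under correlation, all-zero rows under
  cosine. Two all-zero rows have jaccard distance 0 and Tanimoto
  similarity 1 (identical molecules), by documented convention.
* Membership row sums are validated at 1e-9; oracle equivalences (counting
  form vs explicit inversion, vectorised vs double-loop distances) are
  asserted at 1e-12.

## Problem sizes

The test suite exercises the full pipeline at n = 500 molecules × 1024
bits for the recovery checks and n ≤ 30 with exhaustive enumeration for
the partitioner oracles; the experiment driver itself is written for
n into the thousands (dense n × n matrices are the binding constraint —
the CSPA co-association graph is inherently quadratic in n). The
paper-scale grid (cluster counts 500–1000 on ~8300 molecules) is
configurable through `run_config()` but not exercised in tests.

## Known limitations

* CSPA's spectral bisection is a heuristic: it is exact on
  block-structured co-association matrices (the important consensus case)
  and near-optimal on small random instances, but carries no approximation
  guarantee.
* HGPA's balance cap can force cluster fragmentation when true class sizes
  are far from n/k; this is a property of the method's formulation, not of
  the implementation.
* The Lloyd k-means under hamming/jaccard uses bitwise-majority centroids;
  for the jaccard objective the majority vote is a good but not exact
  minimiser.
* Count-valued fingerprints are rejected, not thresholded; fingerprint
  computation from structures is out of scope — matrices are consumed
  precomputed.
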