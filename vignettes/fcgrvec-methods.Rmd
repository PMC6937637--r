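---
title: "Methods: FCGR spectral embeddings for alignment-free genome comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FCGR spectral embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgrvec)
```

## The pipeline and its assumptions

`fcgrvec` compares nucleotide sequences by their k-mer composition
alone. The working assumption is that taxonomically close genomes have
similar k-mer frequency profiles — an assumption that holds well for
sequences of a few kilobases and up, and progressively breaks down for
very short fragments, for heavily horizontally-transferred material,
and across regions of strong compositional heterogeneity. Nothing in
the pipeline requires sequences to share a common length, and no
alignment is ever computed.

A sequence travels through three stages:

**FCGR.** The chaos game assigns corners of the unit square as
A = (0,0), C = (0,1), G = (1,1), T = (1,0) and iterates
\(p_{i} = (p_{i-1} + \mathrm{corner}(s_i))/2\) from the center. Binned
at resolution \(2^k\), the final pixel of the walk depends only on the last
\(k\) bases, so the binned trajectory tallies every k-mer: pixel
coordinates are built bitwise (G/T set an x bit, C/G set a y bit), the
last base contributing the most significant bit. This closed form is
verified in the tests against the literal midpoint iteration. Counts
are max-normalized and taken to the 1/5 power for display; the
nonlinear rescaling keeps sparse images from rendering nearly black
but plays no role downstream (the DCT consumes the rescaled image, and
its scale cancels in distance comparisons only up to normalization, so
the same rescaling must be used for training and queries — the
pipeline functions guarantee this).

**DCT-IV.** The image is centered by its global mean, which removes
the DC component, then transformed separably (rows, then columns —
the order is irrelevant by symmetry and fixed for determinism) with
the orthonormal DCT-IV
\(X_j = \sqrt{2/N}\,\sum_i x_i \cos(\pi(i+\tfrac12)(j+\tfrac12)/N)\).
With this scaling the transform is exactly its own inverse, which the
tests assert to \(10^{-10}\). The top-left \(f \times f\) block is
kept. DCT-IV has no pure-DC basis vector, so "low frequency" is taken
as the lowest-index block after centering; truncating before or after
the second 1-D pass gives the identical block, and we slice after both
passes. The transform is implemented as a cached orthonormal
matrix product — exact, simple, and fast at the image sizes involved
(\(N \le 4096\)); an FFT-based route would only matter far above the
default \(N = 128\).

**Truncated SVD.** Blocks are flattened by appending rows, each vector
centered by its own mean, and stacked into \(M\). We keep the top
\(r\) right-singular vectors \(V\) and store the embedded rows as
\(MV\) rather than computing \(UW\) separately: the two are equal at
full rank, and using \(MV\) keeps training and query vectors on the
identical code path under truncation (a query is centered by *its own*
mean, exactly like a training row — no training-mean is applied).
Singular-vector signs are arbitrary, so each column of \(V\) is
flipped to make its largest-magnitude entry positive; this makes
archives, the Gram-matrix variant, and the subsampled variant directly
comparable.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 7 | pixelation level; image side \(2^k\) = 128. Levels 7–10 behave similarly; 7 keeps the image (16384 px) and memory small. |
| `f` | 30 | retained DCT frequencies per dimension. FCGR images are fractal-like and need more frequencies than natural images; 30 gives a ~18.2x compression with little downstream loss. |
| `r` | 40 | embedding rank for lookup and trees; 20–50 behaves similarly, returns diminish above 40. 80 is conventionally reserved for training downstream classifiers. |
| `chunk_len` | 20000 bp | fragment length for chunked protocols; accuracy rises with length (see the length sweep in the acceptance script). |
| `max_chunks` | 37 | cap on chunks per genome, placed non-overlapping and approximately equally spaced. |
| `K_pool` | 20 | candidate-pool depth for "correct label among the top K". |
| `n_neighbors`, `min_count` | 28, 2 | host-prediction consensus: genera appearing at least twice among the 28 nearest bacterial chunks; chosen so the mean number of guesses lands near three, and re-calibratable with `calibrate_neighbor_count()`. |
| `lookup_metric` | euclidean | the kd-tree metric. |
| `tree_metric`, `linkage` | cosine, average | tree construction; cosine tends to group taxa slightly better than Manhattan. |

## Deterministic conventions and numerical choices

Several choices are open in principle; each is fixed for
reproducibility:

* **Corner assignment.** Any placement with purines across one
  diagonal gives the same distances up to a consistent pixel
  permutation; we fix Jeffrey's convention (A bottom-left, row 1 of
  the matrix at the top). Its exact symmetry — complementing a k-mer
  mirrors its pixel left-right — is enumerated in the tests. (The
  reverse complement induces *no* rigid pixel motion: reversal
  permutes bit significance.)
* **Ambiguity codes.** A length-k window containing any non-ACGT
  IUPAC code contributes to no pixel; the skipped fraction is recorded
  on the count matrix. Inventing fractional counts for ambiguous
  windows would bias pixel totals in composition-dependent ways.
* **Chunk placement.** "Approximately equally spaced" is pinned to
  `start_i = floor(i (len - chunk_len) / (c - 1))`, which provably
  never overlaps since the spacing is at least `chunk_len`.
* **Stitching.** Short-read composites partition fragments into groups
  of `group_size`, fill a matrix row-wise and transpose, so stitched
  sequence *j* takes every `group_size`-th fragment starting at *j* —
  each composite samples the whole genome rather than one locality.
* **Tie-breaks.** kd-tree neighbors are ordered lexicographically by
  (distance, insertion index) and match a brute-force scan exactly;
  majority votes break ties by smallest best distance, then
  lexicographically; consensus sets order by count, best distance,
  label; calibration prefers the smaller neighbor count.
* **Top-K pools** do not deduplicate chunks originating from the same
  training genome; a genome dominating a query's neighborhood
  therefore occupies several pool slots.
* **Degenerate inputs.** All-zero count matrices map to all-zero
  images (no 0/0); eigenvalue round-off is clamped at zero in the
  Gram-matrix SVD and in classical MDS (relative threshold
  \(10^{-12}\), so exactly-degenerate MDS axes are exactly zero);
  genomes shorter than `chunk_len` chunk to nothing with a warning;
  `K` larger than the index clamps with a warning.
* **Solvers.** Dense LAPACK `svd()`/`eigen()` are used throughout: at
  column dimension \(f^2 = 900\) a dense decomposition of even a few
  tens of thousands of rows is cheap, and the two scalability variants
  (row subsampling; Gram matrix) cover the large-\(m\) regime without
  an iterative solver.

## What the synthetic generator does and does not emulate

`make_species()` draws order-2 Markov transition tables over
{A,C,G,T} from a symmetric Dirichlet (`concentration = 1`). Order 2 is
strong enough to give species distinct 7-mer profiles while staying
cheap to sample; lower concentration separates species more.
`sample_genome()` is hierarchical: each genome first perturbs its
species table with a Dirichlet recentering of concentration
`genome_kappa = 200` — a few percent of strain-level variation in
local transition probabilities, which is what gives chunks of one
genome their shared "signature" (real genomes show exactly this
self-similarity) — then applies i.i.d. substitutions at
`mutation_rate = 0.02`, a realistic within-species nucleotide
divergence. `make_benchmark()` adds the stratified 75/25 split
(training count rounded down per species), reproducible per seed, with
fresh split seeds permuting membership only.

The generator deliberately omits repeats, GC skew, indels, mobile
elements and horizontal transfer. Passing its benchmarks therefore
shows that the pipeline separates genuinely distinct compositional
signatures and that every stage composes correctly — it does **not**
certify the accuracy figures achievable on real taxonomies, where
between-species distances are far less Dirichlet-uniform. Accuracies
on the synthetic corpora are typically near 100% and should be read as
integration checks, not as performance claims.

## Problem sizes used by the test suite

The default suite runs two fixture scales, chosen to keep a full test
run around half a minute: a 4-species x 6-genome corpus of 100 kb
genomes chunked to 20 kb (classifier, self-similarity and tree
checks), and a 6-species x 12-genome corpus of 100 kb genomes whose
4/20/100 kb prefixes drive the randomized-trial recovery protocol (20
trials at 20 kb, 5 trials elsewhere). The acceptance script re-runs
the same protocol sizes from scratch under the caller's seed.

## Known limitations

* Very short queries (below ~1 kb) carry noisy k-mer profiles; the
  classifier warns below that length. Stitching multiple short
  fragments into composites recovers much of the signal.
* The embedding is fitted once on the training corpus; substantial
  distribution shift between training and query sets degrades the
  projection silently.
* Hierarchical-clustering trees are distance-based cladograms, not
  model-based phylogenies; linkage choice can change topologies
  modestly, and only average linkage is exercised by default.
* The kd-tree is exact but its efficiency decays in high dimension;
  it is intended for the default \(r \approx 40\), not for hundreds of
  dimensions.
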