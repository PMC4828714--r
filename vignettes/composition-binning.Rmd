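---
title: "Composition-based binning of metagenomic contigs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-based binning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compobin)
```

## The problem

Shotgun metagenomic assembly yields contigs from many genomes mixed
together. *Binning* groups those contigs into clusters intended to
represent single genomes, without references. `compobin` does this from
two signals that are approximately constant along a genome but differ
between genomes:

* the **genomic signature** — the vector of oligonucleotide frequencies of
  a contig; and
* the **coverage profile** — the mean read depth of a contig in each
  sequencing library, which co-varies across samples for contigs of the
  same genome.

A third signal, **single-copy marker genes** (40 universal protein
families present exactly once per prokaryotic genome), is used not for
clustering itself but for *correcting* clusters: a family observed twice
in one bin indicates two genomes folded together; two nearby bins with
non-overlapping family sets are likely fragments of one genome.

## The pipeline

1. **Signatures.** For every contig the occurrences of each feature k-mer
   *and its reverse complement* are counted (`count_kmers()`). Features
   are canonical k-mers — the lexicographic minimum of a word and its
   reverse complement — so signatures are strand-invariant. Three schemes
   exist: 136 canonical tetramers (`4mer`, the default), 512 canonical
   pentamers (`5mer`), and the pentamers plus the 64 palindromic hexamers
   (`5p6mer`, 576 features). Windows containing N are skipped. One
   pseudocount is added, counts are normalized to frequencies, and each
   row is mapped by the centered log-ratio (CLR) transform
   `log(x / geometric_mean(x))` (`clr_transform()`); CLR rows sum to
   zero. Depth profiles, when given, are CLR-transformed per contig with
   the geometric mean taken over *non-zero* depths only
   (`clr_coverage()`) and appended unweighted (`contig_features()`).
2. **Embedding.** The feature matrix is reduced to 2-D by t-SNE
   (`embed_tsne()`) with perplexity 20 and no PCA preprocessing.
3. **Clustering.** Similarities between embedded points are negative
   squared Euclidean distances, sparsified at a squared-distance cutoff
   (`st`, default 500); pairs at or beyond the cutoff are disconnected
   (`sparse_similarity()`). Affinity propagation
   (`affinity_propagation()`) with damping 0.8, `convits` 15 and
   `maxits` 1000 then picks exemplars and clusters; disconnected
   components are clustered independently.
4. **Correction.** With a marker annotation available, clusters whose
   profile shows more than two duplicated families are split in two by
   spectral clustering on their 2-D coordinates; adjacent clusters whose
   merged profile has at most two duplicated families are merged, nearest
   centroid pair first; split and merge alternate to a fixed point
   (`correct_clusters()`).
5. **Two-stage assignment.** Affinity propagation is quadratic in memory,
   so only the longest `lt` fraction of contigs (default 0.7) is
   clustered; each remaining short contig then takes the label of its
   nearest stage-1 contig in CLR tetramer space (`assign_stage2()`),
   tetramers regardless of the stage-1 scheme, since short sequences
   support short words best.

Final clusters are renumbered by decreasing total length; outputs are
per-cluster FASTA files, a contig-to-cluster table, 2-D coordinates for
plotting, and a summary with per-bin genome size, N50, contig count and
distinct marker count (`write_bins()`, `bin_summary()`).

## Evaluation

Against a gold standard, with `S[i, j]` the total length of contigs in
cluster *i* from genome *j* (`binning_contingency()`):

* precision `= 100 · Σᵢ maxⱼ S[i,j] / Σᵢⱼ S[i,j]`,
* recall `= 100 · Σⱼ maxᵢ S[i,j] / Σⱼ Tⱼ`, where `Tⱼ` is the *total*
  gold length of genome *j* including contigs that were never binned —
  recall is measured against whole genomes,
* F1 `= 2PR/(P+R)` (`binning_scores()`, `f1_score()`).

Per-cluster precision and per-genome recall are reported alongside.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_length` | 1000 bp | contigs below this are discarded at read time; shorter sequences have noisy signatures |
| `scheme` | `4mer` | signature resolution; larger schemes need longer contigs to fill 512–576 features |
| `lt` | 0.7 | fraction of contigs clustered in stage 1 (by length rank); `lt = 1` is one-stage mode |
| `st` | 500 | squared-distance cutoff in embedding units; also the centroid adjacency cutoff for merging. Data-scale dependent: dense embeddings of very large assemblies warrant smaller values |
| `perplexity` | 20 | effective t-SNE neighborhood size |
| `preference` | median of finite similarities | affinity-propagation exemplar preference; higher values yield more, smaller clusters before correction |
| `damping`, `convits`, `maxits` | 0.8, 15, 1000 | message-passing stability and stopping |
| `seed` | 42 | pins the stochastic embedding; identical seeds give byte-identical partitions |

## Numerical and design choices

* **Exact t-SNE gradients.** The embedding minimizes the standard KL
  objective with momentum gradient descent, adaptive gains, early
  exaggeration 12 until iteration 250, momentum 0.5→0.8 at iteration
  250, and learning rate 200 (the reference defaults). Gradients are
  computed exactly over all pairs; the Barnes-Hut `theta` parameter is
  recorded for provenance but no tree approximation is applied. At the
  problem sizes this package targets — stage-1 sets of a few hundred to
  a few thousand contigs — the quadratic exact gradient is affordable
  and avoids approximation error. The KL divergence is recorded every 50
  iterations; a momentum optimizer may overshoot transiently between
  checkpoints by a fraction of a percent, which the test suite allows
  for (1% relative) while still requiring overall descent.
* **Affinity propagation in-package.** The responsibility/availability
  updates are implemented directly (vectorized, dense matrices with
  `-Inf` encoding absent edges, which reproduces sparse semantics
  exactly); the test suite checks the result label-for-label against an
  independently written loop-based dense implementation. Assignment ties
  break to the lowest point index; no jitter is added to similarities.
  Fully isolated points (no finite similarity) are returned as
  singletons rather than entering message passing, where they would
  produce infinite self-responsibilities.
* **Spectral splitting.** The affinity is an RBF kernel on the 2-D
  coordinates with bandwidth equal to the median within-cluster pairwise
  distance; the top two eigenvectors of the normalized adjacency are
  row-normalized and bipartitioned by k-means seeded deterministically
  with the two spectrally farthest members. Clusters of size < 2, or
  with all points coincident, are left unchanged with a warning.
* **Correction semantics.** "More than two duplicate marker genes" is
  read as: the number of families with ≥ 2 copies exceeds 2 — the same
  quantity bounds a legal merge (merged duplicated ≤ 2), making split
  and merge mutually consistent: a merge can never recreate what a split
  just removed, which (with splits strictly shrinking clusters)
  guarantees termination; a cycle guard caps passes at 100.
  "Adjacent" is operationalized as mutually-nearest cluster centroids
  or centroid squared distance below `st`.
* **Zero depths.** Coverage CLR excludes zeros from the geometric mean
  and encodes them as 0 — the CLR value of a depth equal to the row
  geometric mean, the least-informative finite choice. A single-sample
  depth table therefore contributes a constant column (log of depth over
  itself); coverage helps only with two or more libraries.
* **Cluster numbering** is 1..K by decreasing bin length — arbitrary but
  deterministic, which the round-trip tests rely on.

## The synthetic community generator

`generate_community()` builds desk-scale fixtures with the statistical
structure the binner exploits, and writes exactly the file formats the
readers consume. Each genome is simulated from its own random order-3
Markov chain (Dirichlet-style random transition rows), which yields
distinct, genome-wide-coherent tetranucleotide signatures of realistic
contrast at negligible cost. Genomes are fragmented into lognormal
contigs (meanlog `log(8000)`, sdlog 0.7, truncated at 1000 bp — giving
roughly 100 contigs per Mb, a typical short-read assembly granularity).
Per-sample genome abundances follow a power-law series (exponent 0.75,
rank order permuted independently per sample, scale 50×), so coverage
profiles are informative across libraries; per-contig depths add
lognormal noise with cv 0.1. Each genome carries exactly one copy of
each of the 40 single-copy families, placed on uniformly random contigs.

What the generator does **not** emulate: read-level sequencing error and
the assembly process (chimeric contigs, uneven fragment lengths at
repeats), strain mixtures, horizontal transfer, GC-dependent coverage
bias, and conserved inter-genome homology. Passing the recovery tests
therefore demonstrates the pipeline's correctness and its behavior under
idealized signal strengths, not field performance on real assemblies.

## Problem sizes used in the test suite

Unit fixtures use tens to hundreds of points. The end-to-end recovery
standard is a 10-genome community of 1 Mb genomes with 4 libraries
(≈ 980 contigs, ≈ 690 in stage 1), on which the pipeline is expected to
reach ≥ 95% precision and recall with 10 ± 2 bins; the packaged
acceptance script (`scripts/acceptance.R`) re-runs exactly this
computation from scratch. Smaller 3–4-genome communities back the
per-module tests.

## Known limitations

* Dense message passing stores O(N²) doubles; stage-1 sets beyond
  ~20,000 contigs are impractical — raise `lt`'s complement (more
  stage-2 contigs) or subsample rather than feeding very large
  assemblies directly.
* Exact t-SNE is quadratic per iteration; very large stage-1 sets are
  slow.
* Marker annotation is consumed as a precomputed table (gene prediction
  and HMM extraction are external); without it, correction is skipped
  and over-fragmentation must be resolved by the preference parameter.
* Closely related genomes (≥ species-level relatedness) have similar
  signatures and may not separate, as is inherent to composition-based
  binning.
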