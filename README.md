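# compobin

Reference-free binning of assembled metagenomic contigs into genome
bins, for microbiome researchers who have an assembly (and optionally
per-library read depths and a single-copy marker-gene annotation) and
want per-genome FASTA bins with quality summaries.

## Method

Each contig of length ≥ 1000 bp is represented by its **canonical k-mer
signature**: counts of every feature k-mer and its reverse complement
(136 canonical tetramers by default; 512 canonical pentamers or
512 + 64 palindromic hexamers optionally), pseudocounted, normalized,
and mapped by the centered log-ratio transform

    clr(x)_i = log( x_i / g(x) ),   g(x) = (∏_j x_j)^(1/D)

Per-library depth profiles, when available, are CLR-transformed over
their non-zero entries and appended. The feature matrix is embedded in
2-D by t-SNE (perplexity 20, no PCA), and the embedded points are
clustered by affinity propagation on negative squared Euclidean
distances sparsified at a squared-distance cutoff (default 500), with
damping 0.8, `convits` 15, `maxits` 1000. Clusters are then corrected
with single-copy marker genes — a cluster with more than two duplicated
families is split by spectral clustering; adjacent clusters whose union
has at most two duplicated families are merged — and the short contigs
excluded from stage 1 (the shortest 30% by default) are assigned to the
bin of their nearest neighbor in CLR tetramer space.

Binning quality against a gold standard is scored length-weighted, with
`S[i][j]` the total length of contigs in cluster *i* from genome *j*:

    precision = 100 · Σ_i max_j S[i][j] / Σ_ij S[i][j]
    recall    = 100 · Σ_j max_i S[i][j] / Σ_j T_j      (T_j = full gold length of genome j)
    F1        = 2·P·R / (P + R)

## Worked example

Generate a small synthetic community (4 genomes × 250 kb, 3 libraries),
bin it, and score the result:

```r
library(compobin)

comm <- generate_community(community_spec(
  n_genomes = 4, genome_length = 250000, n_samples = 3, seed = 11))
res <- bin_contigs(comm$contigs, depths = comm$depths,
                   markers = comm$markers, seed = 5, verbose = TRUE)
#> [bin] 95 contigs; stage 1 clusters the 67 longest (lt = 0.7)
#> [bin] feature matrix: 67 x 139 (4mer + coverage)
#> [bin] embedded; final KL = 0.3372
#> [bin] affinity propagation: 14 clusters
#> [bin] marker correction: 4 clusters
#> [bin] stage 2 assigned 28 short contigs

binning_scores(binning_contingency(
  setNames(res$assignment$cluster, res$assignment$contig_id),
  comm$gold, contig_lengths(comm$contigs)))
#> precision 100.00%  recall 100.00%  F1 100.0 (4 clusters, 4 genomes)
```

Affinity propagation over-segments the embedding (14 clusters); the
marker-driven merge step collapses same-genome fragments into exactly
the 4 genomes, every contig ends up with its own genome, and
precision = recall = 100%. `write_bins()` then writes one
`Cluster.<i>.fasta` per bin plus `bins.tsv` and `coordinates.tsv`, and
`bin_summary()` reports per-bin `WholeGenome`, `N50`, `NoOfCtg` and
`Cogs` (distinct marker families, ≤ 40).

The same pipeline runs from the shell via the bundled CLI:

```sh
Rscript inst/scripts/compobin.R synth --outdir demo --n-genomes 4
Rscript inst/scripts/compobin.R bin demo/contigs.fasta -a demo/depth.tsv \
    -m demo/markers.tsv -o demo/out --seed 5
Rscript inst/scripts/compobin.R eval --bins demo/out/bins.tsv \
    --gold demo/gold.tsv --fasta demo/contigs.fasta
```

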