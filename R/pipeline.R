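#' Bin metagenomic contigs
#'
#' The full binning pipeline. A fraction `lt` of the contigs — the longest
#' `ceiling(lt * N)` by length, ties by input order — is clustered in
#' stage 1: CLR-transformed canonical k-mer signatures (optionally fused
#' with CLR depth profiles) are embedded in 2-D by t-SNE
#' ([embed_tsne()]), the embedded points are clustered by affinity
#' propagation over a distance-cutoff sparsified similarity graph
#' ([sparse_similarity()], [affinity_propagation()]), and, when a marker
#' annotation is supplied, clusters are corrected by marker-driven
#' splitting and merging ([correct_clusters()]). In stage 2 each
#' remaining short contig is assigned to the cluster of its nearest
#' stage-1 contig in CLR tetramer space ([assign_stage2()]). Final
#' clusters are renumbered 1..K by decreasing total length.
#'
#' @param contigs A [contig_set()] (or anything [contig_features()]
#'   accepts).
#' @param depths Optional depth matrix (contig ids as row names), as from
#'   [read_depth_table()].
#' @param markers Optional marker annotation (named list), as from
#'   [read_marker_table()]; without it, cluster correction is skipped.
#' @param scheme K-mer scheme name for stage 1: `"4mer"` (default),
#'   `"5mer"`, `"5p6mer"`.
#' @param lt Stage-1 fraction of contigs, in (0, 1]; default 0.7. `lt = 1`
#'   is one-stage mode.
#' @param st Squared-distance sparsification cutoff for the similarity
#'   graph and the merge adjacency test (default 500).
#' @param perplexity t-SNE perplexity (default 20).
#' @param seed Integer seed pinning the stochastic embedding (default 42).
#' @param preference Affinity-propagation preference (default
#'   `"median"`).
#' @param maxits,convits,damping Affinity-propagation controls (defaults
#'   1000, 15, 0.8).
#' @param verbose Log stage progress to stderr.
#' @return A list of class `binning`: `assignment` (data frame with
#'   `contig_id`, `cluster`, `stage`), `coords` (stage-1 2-D embedding),
#'   `embedding` (the full [embed_tsne()] result), `ap` (the
#'   [affinity_propagation()] result), `n_clusters`, and `params`.
#' @export
bin_contigs <- function(contigs, depths = NULL, markers = NULL,
                        scheme = "4mer", lt = 0.7, st = 500,
                        perplexity = 20, seed = 42, preference = "median",
                        maxits = 1000, convits = 15, damping = 0.8,
                        verbose = FALSE) {
  if (!(lt > 0 && lt <= 1)) stop("lt must be in (0, 1]")
  if (!inherits(contigs, "contig_set"))
    contigs <- contig_set(as.character(as_dna(contigs)) |>
                            stats::setNames(names(as_dna(contigs))),
                          min_length = 0)
  say <- function(...) if (verbose) message("[bin] ", ...)
  lens <- contig_lengths(contigs)
  n <- length(lens)
  n1 <- ceiling(lt * n)
  stage1 <- sort(order(-lens, seq_len(n))[seq_len(n1)])
  say(n, " contigs; stage 1 clusters the ", n1, " longest (lt = ", lt, ")")

  feats <- contig_features(contigs[stage1], scheme = scheme,
                           depths = if (is.null(depths)) NULL else
                             depths[contig_ids(contigs[stage1]), , drop = FALSE])
  say("feature matrix: ", nrow(feats), " x ", ncol(feats), " (", scheme,
      if (!is.null(depths)) " + coverage", ")")

  emb <- embed_tsne(feats, perplexity = perplexity, seed = seed)
  say("embedded; final KL = ", signif(utils::tail(emb$costs$cost, 1L), 4))

  sim <- sparse_similarity(emb$coords, threshold = st)
  ap <- affinity_propagation(sim, preference = preference, maxits = maxits,
                             convits = convits, damping = damping)
  labels <- relabel(ap$labels)
  say("affinity propagation: ", length(unique(labels)), " clusters")

  if (!is.null(markers)) {
    labels <- correct_clusters(labels, emb$coords, markers, st = st)
    say("marker correction: ", length(unique(labels)), " clusters")
  } else {
    say("no marker annotation; cluster correction skipped")
  }

  stage <- stats::setNames(rep("stage1", n1), names(labels))
  if (n1 < n) {
    short_ids <- contig_ids(contigs)[-stage1]
    sig4_all <- clr_transform(count_kmers(contigs, "4mer"))
    s2 <- assign_stage2(sig4_all[short_ids, , drop = FALSE],
                        sig4_all[names(labels), , drop = FALSE], labels)
    labels <- c(labels, s2)
    stage <- c(stage, stats::setNames(rep("stage2", length(s2)), names(s2)))
    say("stage 2 assigned ", length(s2), " short contigs")
  }

  # renumber 1..K by decreasing total bin length
  sizes <- tapply(lens[names(labels)], labels, sum)
  new_id <- stats::setNames(seq_along(sizes), names(sort(-sizes)))
  labels <- stats::setNames(new_id[as.character(labels)], names(labels))
  labels <- labels[contig_ids(contigs)]   # back to input order
  stage <- stage[names(labels)]

  structure(
    list(assignment = data.frame(contig_id = names(labels),
                                 cluster = unname(labels),
                                 stage = unname(stage)),
         coords = emb$coords, embedding = emb, ap = ap,
         n_clusters = length(unique(labels)),
         params = list(scheme = if (is.character(scheme)) scheme else scheme$name,
                       lt = lt, st = st, perplexity = perplexity,
                       seed = seed, preference = preference,
                       coverage = !is.null(depths),
                       corrected = !is.null(markers))),
    class = "binning"
  )
}

#' @export
print.binning <- function(x, ...) {
  cat("binning: ", nrow(x$assignment), " contigs in ", x$n_clusters,
      " clusters (scheme ", x$params$scheme,
      if (x$params$coverage) " + coverage", ", lt ", x$params$lt,
      ", seed ", x$params$seed, ")\n", sep = "")
  invisible(x)
}

# Named cluster vector of a binning result.
binned_clusters <- function(binning) {
  stats::setNames(binning$assignment$cluster, binning$assignment$contig_id)
}

#' Run the binning pipeline on files
#'
#' File-level wrapper around [bin_contigs()]: reads the FASTA (and
#' optional depth/marker tables), bins, and writes per-cluster FASTA
#' files, the contig-to-cluster table, the 2-D coordinates table, and the
#' bin summary into `outdir`.
#'
#' @param fasta Path to the assembled contigs (FASTA, plain or gzipped).
#' @param outdir Output directory.
#' @param depth Optional depth table path.
#' @param depth_dialect Depth table dialect (see [read_depth_table()]).
#' @param marker Optional marker annotation path.
#' @param min_length Minimum contig length in bp (default 1000).
#' @inheritParams bin_contigs
#' @return Invisibly, the [bin_contigs()] result.
#' @export
run_binning <- function(fasta, outdir, depth = NULL,
                        depth_dialect = "plain", marker = NULL,
                        min_length = 1000, scheme = "4mer", lt = 0.7,
                        st = 500, perplexity = 20, seed = 42,
                        verbose = TRUE) {
  contigs <- read_contigs(fasta, min_length = min_length)
  depths <- if (is.null(depth)) NULL else
    match_depths(read_depth_table(depth, dialect = depth_dialect),
                 contig_ids(contigs))
  markers <- if (is.null(marker)) NULL else read_marker_table(marker)
  res <- bin_contigs(contigs, depths = depths, markers = markers,
                     scheme = scheme, lt = lt, st = st,
                     perplexity = perplexity, seed = seed, verbose = verbose)
  write_bins(res, contigs, outdir)
  summ <- bin_summary(res, contigs, markers)
  data.table::fwrite(summ, file.path(outdir, "summary.tsv"), sep = "\t")
  if (verbose)
    message("[bin] wrote ", res$n_clusters, " clusters to ", outdir)
  invisible(res)
}

#' Evaluate a binning against a gold standard, from files
#'
#' @param bins Path to a contig-to-cluster TSV (`bins.tsv` layout:
#'   header, contig_id, cluster).
#' @param gold Path to the gold-standard TSV (contig_id, genome; no
#'   header).
#' @param fasta Path to the contigs FASTA providing lengths.
#' @param out Optional path for a TSV report ([write_eval_report()]).
#' @return The [binning_scores()] result.
#' @export
run_evaluation <- function(bins, gold, fasta, out = NULL) {
  tab <- data.table::fread(bins, sep = "\t", header = TRUE, data.table = FALSE)
  assignment <- stats::setNames(tab[[2L]], as.character(tab[[1L]]))
  truth <- read_gold_standard(gold)
  if (length(intersect(names(assignment), names(truth))) == 0L)
    stop("no contig ids shared between bins and gold standard")
  lens <- contig_lengths(read_contigs(fasta, min_length = 0))
  scores <- binning_scores(binning_contingency(assignment, truth, lens))
  if (!is.null(out)) write_eval_report(scores, out)
  print(scores)
  invisible(scores)
}
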