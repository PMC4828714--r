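#' Length-weighted cluster-by-genome contingency table
#'
#' `S[i, j]` is the total length (bp) of contigs placed in cluster `i`
#' whose gold-standard genome is `j`. Genome totals count the full gold
#' length of each genome, including contigs the binner did not bin, so
#' that recall is measured against the whole genome.
#'
#' @param assignment Named integer/character vector: cluster per binned
#'   contig.
#' @param gold Named character vector: genome per contig (the gold
#'   standard), as from [read_gold_standard()].
#' @param lengths Named numeric vector of contig lengths in bp covering
#'   every contig in `assignment` and `gold`.
#' @return A list of class `bin_contingency`: `S` (clusters x genomes
#'   length matrix) and `genome_totals` (named vector).
#' @export
binning_contingency <- function(assignment, gold, lengths) {
  binned <- names(assignment)
  nogold <- setdiff(binned, names(gold))
  if (length(nogold)) {
    warning(length(nogold), " binned contig(s) absent from the gold ",
            "standard were dropped: ",
            paste(utils::head(nogold, 5L), collapse = ", "))
    binned <- setdiff(binned, nogold)
    assignment <- assignment[binned]
  }
  need <- union(binned, names(gold))
  if (anyNA(lengths[need]))
    stop("missing contig length(s): ",
         paste(utils::head(need[is.na(lengths[need])], 5L), collapse = ", "))
  clusters <- sort(unique(as.character(assignment)))
  genomes <- sort(unique(unname(gold)))
  S <- matrix(0, length(clusters), length(genomes),
              dimnames = list(clusters, genomes))
  for (ct in binned)
    S[as.character(assignment[[ct]]), gold[[ct]]] <-
      S[as.character(assignment[[ct]]), gold[[ct]]] + lengths[[ct]]
  totals <- stats::setNames(
    as.numeric(tapply(lengths[names(gold)], unname(gold), sum)[genomes]),
    genomes)
  structure(list(S = S, genome_totals = totals), class = "bin_contingency")
}

#' Overall binning precision, recall and F1
#'
#' Length-weighted scores against a gold standard. With `S[i, j]` the
#' total length of contigs in cluster `i` from genome `j`:
#'
#' * precision = `100 * sum_i max_j S[i,j] / sum_ij S[i,j]` — the fraction
#'   of binned length belonging to each cluster's dominant genome;
#' * recall = `100 * sum_j max_i S[i,j] / sum_j genome_total[j]` — the
#'   fraction of total gold length recovered by each genome's best
#'   cluster;
#' * F1 = the harmonic mean `2 P R / (P + R)`.
#'
#' Per-cluster precision and per-genome recall are reported alongside.
#'
#' @param contingency A `bin_contingency` from [binning_contingency()],
#'   or a plain length matrix `S` (then `genome_totals` must be given).
#' @param genome_totals Named vector of gold genome lengths; defaults to
#'   the totals stored in `contingency`.
#' @return A list of class `bin_scores`: `precision`, `recall`, `f1` (all
#'   percentages), `per_cluster` (data frame: cluster, best-match genome,
#'   precision %), `per_genome` (data frame: genome, best cluster,
#'   recall %).
#' @examples
#' f1_score(86.72, 98.68)  # 92.3, to one decimal
#' @export
binning_scores <- function(contingency, genome_totals = NULL) {
  if (inherits(contingency, "bin_contingency")) {
    S <- contingency$S
    if (is.null(genome_totals)) genome_totals <- contingency$genome_totals
  } else S <- as.matrix(contingency)
  if (is.null(genome_totals)) stop("genome_totals required")
  if (sum(S) == 0 || sum(genome_totals) == 0) stop("zero total length")
  cl_best <- apply(S, 1L, max)
  g_best <- apply(S, 2L, max)
  precision <- 100 * sum(cl_best) / sum(S)
  recall <- 100 * sum(g_best) / sum(genome_totals)
  structure(
    list(
      precision = precision, recall = recall,
      f1 = f1_score(precision, recall),
      per_cluster = data.frame(
        cluster = rownames(S),
        genome = colnames(S)[apply(S, 1L, which.max)],
        precision = 100 * cl_best / rowSums(S),
        row.names = NULL),
      per_genome = data.frame(
        genome = colnames(S),
        cluster = rownames(S)[apply(S, 2L, which.max)],
        recall = 100 * g_best / as.numeric(genome_totals[colnames(S)]),
        row.names = NULL)
    ),
    class = "bin_scores"
  )
}

#' Harmonic-mean F1 score
#'
#' @param precision,recall Percentages.
#' @return `2 * precision * recall / (precision + recall)`.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @export
print.bin_scores <- function(x, ...) {
  cat(sprintf("precision %.2f%%  recall %.2f%%  F1 %.1f (%d clusters, %d genomes)\n",
              x$precision, x$recall, x$f1,
              nrow(x$per_cluster), nrow(x$per_genome)))
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes a TSV with the overall precision/recall/F1 line followed by the
#' per-cluster precision and per-genome recall tables.
#'
#' @param scores A `bin_scores` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("overall\tprecision=%.4f\trecall=%.4f\tF1=%.4f",
                     scores$precision, scores$recall, scores$f1), con)
  writeLines("#cluster\tbest_genome\tprecision", con)
  writeLines(sprintf("%s\t%s\t%.4f", scores$per_cluster$cluster,
                     scores$per_cluster$genome, scores$per_cluster$precision), con)
  writeLines("#genome\tbest_cluster\trecall", con)
  writeLines(sprintf("%s\t%s\t%.4f", scores$per_genome$genome,
                     scores$per_genome$cluster, scores$per_genome$recall), con)
  invisible(path)
}
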