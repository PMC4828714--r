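#' Marker-gene profile of a cluster
#'
#' Tabulates the single-copy marker-gene families carried by a set of
#' contigs. Because each family occurs once per prokaryotic genome,
#' families with two or more copies inside one cluster indicate
#' contamination (two genomes folded together), while the number of
#' distinct families present indicates completeness.
#'
#' @param members Character vector of contig ids.
#' @param markers Marker annotation: named list of family-id vectors, as
#'   from [read_marker_table()].
#' @return A list: `counts` (named integer vector of per-family copy
#'   numbers), `distinct` (families present), `duplicated` (families with
#'   >= 2 copies).
#' @export
marker_profile <- function(members, markers) {
  fams <- unlist(markers[intersect(members, names(markers))], use.names = FALSE)
  counts <- if (length(fams)) table(fams) else table(character(0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       distinct = length(counts),
       duplicated = sum(counts >= 2L))
}

#' Split a contaminated cluster by spectral bipartition
#'
#' Partitions the member contigs of one cluster into two non-empty groups
#' by normalized spectral clustering (k = 2) on their 2-D embedding
#' coordinates with an RBF affinity whose bandwidth is the median pairwise
#' distance within the cluster. Intended for clusters whose marker profile
#' shows more than two duplicated families.
#'
#' @param members Character vector of member contig ids.
#' @param coords 2-D coordinate matrix with contig ids as row names.
#' @return A list of two character vectors (the two child clusters), or
#'   `NULL` with a warning when the cluster cannot be split (fewer than 2
#'   members, or all points coincident).
#' @export
split_cluster <- function(members, coords) {
  if (length(members) < 2L) {
    warning("cluster of size ", length(members), " cannot be split")
    return(NULL)
  }
  y <- as.matrix(coords[members, , drop = FALSE])
  d <- as.matrix(stats::dist(y))
  med <- stats::median(d[upper.tri(d)])
  if (!is.finite(med) || med == 0) {
    warning("all points coincident; cluster cannot be split")
    return(NULL)
  }
  aff <- exp(-d^2 / (2 * med^2))
  diag(aff) <- 0
  dg <- 1 / sqrt(pmax(rowSums(aff), .Machine$double.eps))
  lap <- aff * (dg %o% dg)                 # normalized adjacency D^-1/2 A D^-1/2
  ev <- eigen(lap, symmetric = TRUE)
  u <- ev$vectors[, 1:2, drop = FALSE]
  norm <- sqrt(rowSums(u^2))
  u <- u / pmax(norm, .Machine$double.eps)
  # deterministic k-means: seed with the two spectrally farthest members
  du <- as.matrix(stats::dist(u))
  far <- arrayInd(which.max(du), dim(du))
  km <- stats::kmeans(u, centers = u[c(far[1L], far[2L]), , drop = FALSE],
                      iter.max = 100L)
  grp <- km$cluster
  if (length(unique(grp)) < 2L) grp <- as.integer(u[, 2L] >= stats::median(u[, 2L])) + 1L
  split(members, grp)
}

#' Merge adjacent complementary clusters
#'
#' Candidate pairs of clusters are merged greedily in order of increasing
#' centroid distance. A pair qualifies when it is *adjacent* — the two
#' cluster centroids are mutually nearest among all cluster centroids, or
#' their squared centroid distance is below `st` — and *complementary* —
#' the merged marker profile has at most `max_dup` duplicated families, so
#' the merge does not create a contaminated cluster. Candidates are
#' re-evaluated after every merge.
#'
#' @param labels Named integer vector: cluster id per contig.
#' @param coords 2-D coordinate matrix with contig ids as row names.
#' @param markers Marker annotation (named list of family-id vectors).
#' @param st Squared-distance adjacency cutoff between centroids
#'   (default 500, the similarity sparsification cutoff).
#' @param max_dup Maximum duplicated-family count allowed in a merged
#'   cluster (default 2).
#' @return Updated `labels` (cluster ids of merged clusters are collapsed
#'   onto one of the pair; numbering is not compacted).
#' @export
merge_clusters <- function(labels, coords, markers, st = 500, max_dup = 2L) {
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2L) break
    cent <- t(vapply(ids, function(cl) {
      colMeans(coords[names(labels)[labels == cl], , drop = FALSE])
    }, numeric(2L)))
    d2 <- as.matrix(stats::dist(cent))^2
    diag(d2) <- Inf
    nn <- apply(d2, 1L, which.min)
    mutual <- outer(seq_along(ids), seq_along(ids),
                    function(i, j) nn[i] == j & nn[j] == i)
    adjacent <- (mutual | d2 < st) & upper.tri(d2)
    cand <- which(adjacent, arr.ind = TRUE)
    if (nrow(cand) == 0L) break
    cand <- cand[order(d2[cand]), , drop = FALSE]
    merged <- FALSE
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      both <- names(labels)[labels %in% ids[c(i, j)]]
      if (marker_profile(both, markers)$duplicated <= max_dup) {
        labels[labels == ids[j]] <- ids[i]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  labels
}

#' Marker-driven cluster correction
#'
#' Iterates split and merge passes to a fixed point: any cluster whose
#' marker profile shows more than `max_dup` duplicated single-copy
#' families is split in two by [split_cluster()]; adjacent complementary
#' clusters are merged by [merge_clusters()]. Iteration stops when a full
#' pass changes nothing, or at `max_iter` passes (with a warning). The set
#' of contigs is never changed, only the partition.
#'
#' @inheritParams merge_clusters
#' @param max_iter Iteration cap on split+merge passes (default 100).
#' @return Updated `labels`, relabeled 1..K in order of first appearance.
#' @export
correct_clusters <- function(labels, coords, markers, st = 500,
                             max_dup = 2L, max_iter = 100L) {
  for (pass in seq_len(max_iter)) {
    changed <- FALSE
    # split pass
    repeat {
      ids <- unique(labels)
      todo <- ids[vapply(ids, function(cl) {
        members <- names(labels)[labels == cl]
        length(members) >= 2L &&
          marker_profile(members, markers)$duplicated > max_dup
      }, logical(1L))]
      if (length(todo) == 0L) break
      did <- FALSE
      for (cl in todo) {
        members <- names(labels)[labels == cl]
        halves <- split_cluster(members, coords)
        if (is.null(halves)) next
        labels[halves[[2L]]] <- max(labels) + 1L
        changed <- TRUE; did <- TRUE
      }
      if (!did) break
    }
    # merge pass
    merged <- merge_clusters(labels, coords, markers, st = st, max_dup = max_dup)
    if (!identical(merged, labels)) changed <- TRUE
    labels <- merged
    if (!changed) break
  }
  if (pass == max_iter && changed)
    warning("cluster correction stopped at the iteration cap (", max_iter, ")")
  relabel(labels)
}

#' Assign second-stage short contigs to existing bins
#'
#' Each short contig (excluded from first-stage clustering) receives the
#' cluster label of the first-stage contig nearest to it in CLR tetramer
#' signature space (tetramers are used regardless of the first-stage
#' scheme). Ties are broken by the lowest first-stage contig index.
#'
#' @param short_features CLR 4-mer signature matrix of the short contigs
#'   (rows named by contig id).
#' @param stage1_features CLR 4-mer signature matrix of the first-stage
#'   contigs (rows named by contig id).
#' @param stage1_labels Named integer vector: cluster per first-stage
#'   contig.
#' @return Named integer vector: cluster per short contig.
#' @export
assign_stage2 <- function(short_features, stage1_features, stage1_labels) {
  if (length(stage1_labels) == 0L) stop("empty first-stage assignment")
  a <- as.matrix(short_features)
  b <- as.matrix(stage1_features[names(stage1_labels), , drop = FALSE])
  if (nrow(a) == 0L)
    return(stats::setNames(integer(0), character(0)))
  # squared Euclidean distances via the expansion |a|^2 + |b|^2 - 2ab'
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  nearest <- max.col(-d2, ties.method = "first")
  stats::setNames(unname(stage1_labels)[nearest], rownames(a))
}

# Compact cluster ids to 1..K in order of first appearance.
relabel <- function(labels) {
  stats::setNames(match(labels, unique(labels)), names(labels))
}
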