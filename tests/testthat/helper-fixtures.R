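# Shared fixture builders (all generated in code, fixed seeds).

# Two well-separated high-dimensional Gaussian blobs.
make_blobs <- function(n_per = 100, d = 10, sep = 10, seed = 303) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, mean = sep), n_per, d))
    rownames(x) <- sprintf("p%03d", seq_len(2 * n_per))
    list(x = x, labels = rep(1:2, each = n_per))
  })
}

# Random DNA string.
random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# A tiny two-genome marker fixture: two coordinate blobs, each carrying a
# full single-copy marker set, united in one cluster (split fixture) or
# fragmented across several clusters (merge fixture).
make_contaminated_cluster <- function(seed = 71) {
  withr::with_seed(seed, {
    n <- 12
    coords <- rbind(matrix(rnorm(n * 2, 0, 0.5), n, 2),
                    matrix(rnorm(n * 2, 8, 0.5), n, 2))
    ids <- sprintf("c%02d", seq_len(2 * n))
    rownames(coords) <- ids
    markers <- list()
    fams <- marker_families()
    for (g in 1:2) {
      host <- sample(ids[seq_len(n) + (g - 1) * n], length(fams), replace = TRUE)
      for (i in seq_along(fams))
        markers[[host[i]]] <- c(markers[[host[i]]], fams[i])
    }
    list(coords = coords, markers = markers,
         genome = rep(1:2, each = n), ids = ids)
  })
}

# Six adjacent fragments of one genome with disjoint marker families.
make_fragmented_genome <- function(seed = 72) {
  withr::with_seed(seed, {
    centers <- cbind(seq(0, 10, length.out = 6), rep(0, 6))
    coords <- NULL; labels <- integer(0); markers <- list()
    fams <- split(marker_families(), rep(1:6, length.out = 40))
    for (f in 1:6) {
      n <- 5
      ids <- sprintf("f%d_%d", f, 1:n)
      xy <- matrix(rnorm(n * 2, sd = 0.3), n, 2) +
        rep(centers[f, ], each = n)
      rownames(xy) <- ids
      coords <- rbind(coords, xy)
      labels <- c(labels, setNames(rep(f, n), ids))
      host <- sample(ids, length(fams[[f]]), replace = TRUE)
      for (i in seq_along(fams[[f]]))
        markers[[host[i]]] <- c(markers[[host[i]]], fams[[f]][i])
    }
    list(coords = coords, labels = labels, markers = markers)
  })
}

# Write a small FASTA file and return its path.
write_tmp_fasta <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "contigs.fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# Canonical form of a label vector: renumber by first appearance, so two
# clusterings are comparable irrespective of cluster numbering.
canon_labels <- function(l) match(l, unique(l))
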