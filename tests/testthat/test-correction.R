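test_that("marker profiles count copies, distinct and duplicated families", {
  markers <- list(c1 = c("COG0001", "COG0002"),
                  c2 = c("COG0001", "COG0003", "COG0003"),
                  c9 = "COG0040")
  p <- marker_profile(c("c1", "c2"), markers)
  expect_equal(p$counts[["COG0001"]], 2L)
  expect_equal(p$distinct, 3L)
  expect_equal(p$duplicated, 2L)      # COG0001 and COG0003
  expect_equal(marker_profile(c("cX"), markers)$distinct, 0L)
})

test_that("a cluster uniting two genomes is split into clean halves", {
  fx <- make_contaminated_cluster()
  prof <- marker_profile(fx$ids, fx$markers)
  expect_equal(prof$duplicated, 40L)           # two full single-copy sets
  halves <- split_cluster(fx$ids, fx$coords)
  expect_length(halves, 2L)
  expect_true(all(lengths(halves) > 0))
  expect_setequal(unlist(halves), fx$ids)
  for (h in halves)
    expect_lte(marker_profile(h, fx$markers)$duplicated, 2L)
  # the spectral split recovers the two coordinate blobs exactly
  g <- fx$genome[match(halves[[1]], fx$ids)]
  expect_length(unique(g), 1L)
})

test_that("degenerate splits are refused with a warning", {
  expect_warning(out <- split_cluster("only", matrix(0, 1, 2,
    dimnames = list("only", NULL))), "cannot be split")
  expect_null(out)
  co <- matrix(1, 4, 2, dimnames = list(paste0("c", 1:4), NULL))
  expect_warning(out <- split_cluster(paste0("c", 1:4), co), "coincident")
  expect_null(out)
})

test_that("six adjacent complementary fragments merge into one cluster", {
  fx <- make_fragmented_genome()
  merged <- merge_clusters(fx$labels, fx$coords, fx$markers, st = 500)
  expect_equal(length(unique(merged)), 1L)
  expect_equal(names(merged), names(fx$labels))
})

test_that("contaminating or distant merges are refused", {
  fx <- make_contaminated_cluster()
  # two adjacent clusters, each a full single-copy set: merged duplicated
  # would be 40 > 2, so they must not merge
  labels <- setNames(rep(1:2, each = 12), fx$ids)
  out <- merge_clusters(labels, fx$coords, fx$markers, st = 500)
  expect_equal(length(unique(out)), 2L)
  # complementary but far apart and not mutually nearest: no merge.
  # A and B carry disjoint half-sets; C and D are full sets sitting next
  # to A and B respectively, so A's nearest is C and B's nearest is D.
  fams <- marker_families()
  ids <- c(sprintf("a%d", 1:3), sprintf("b%d", 1:3),
           sprintf("c%d", 1:3), sprintf("d%d", 1:3))
  coords <- rbind(matrix(0, 3, 2), matrix(1000, 3, 2),
                  matrix(5, 3, 2), matrix(1005, 3, 2))
  rownames(coords) <- ids
  markers <- list(a1 = fams[1:20], b1 = fams[21:40],
                  c1 = fams, d1 = fams)
  labels <- setNames(rep(1:4, each = 3), ids)
  out <- merge_clusters(labels, coords, markers, st = 3)
  expect_equal(length(unique(out)), 4L)
})

test_that("correction reaches a fixed point with clean clusters", {
  # over-fragmented genome plus one contaminated cluster
  frag <- make_fragmented_genome(seed = 81)
  cont <- make_contaminated_cluster(seed = 82)
  coords <- rbind(frag$coords, cont$coords + 100)
  labels <- c(frag$labels, setNames(rep(7L, length(cont$ids)), cont$ids))
  markers <- c(frag$markers, cont$markers)
  out <- correct_clusters(labels, coords, markers, st = 500)
  expect_setequal(names(out), names(labels))              # conservation
  for (cl in unique(out)) {
    members <- names(out)[out == cl]
    expect_true(marker_profile(members, markers)$duplicated <= 2L ||
                  length(members) == 1L)
  }
  # the fragmented genome collapsed; the contaminated cluster split
  expect_lt(length(unique(out)), length(unique(labels)))
  # already-clean clustering is a fixed point
  again <- correct_clusters(out, coords, markers, st = 500)
  expect_equal(canon_labels(unname(again[names(out)])),
               canon_labels(unname(out)))
})

test_that("correction is stable under permuted cluster ids", {
  frag <- make_fragmented_genome(seed = 83)
  perm <- withr::with_seed(84, sample(6))
  relabeled <- setNames(perm[frag$labels], names(frag$labels))
  a <- correct_clusters(frag$labels, frag$coords, frag$markers)
  b <- correct_clusters(relabeled, frag$coords, frag$markers)
  # identical partitions regardless of incoming numbering
  expect_equal(canon_labels(unname(a[names(frag$labels)])),
               canon_labels(unname(b[names(frag$labels)])))
})

test_that("stage-2 assignment maps short contigs to their nearest signature", {
  withr::with_seed(91, {
    long_seqs <- setNames(vapply(1:6, function(i) random_dna(2000),
                                 character(1)), paste0("L", 1:6))
    sig_long <- clr_transform(count_kmers(long_seqs, "4mer"))
    labels <- setNames(c(1L, 1L, 2L, 2L, 3L, 3L), names(long_seqs))
    # a short contig identical to a stage-1 contig: distance 0, same bin
    sig_short <- sig_long[c(3, 5), , drop = FALSE]
    rownames(sig_short) <- c("s1", "s2")
    out <- assign_stage2(sig_short, sig_long, labels)
    expect_equal(out, c(s1 = 2L, s2 = 3L))
  })
  expect_error(assign_stage2(matrix(0, 1, 2), matrix(0, 1, 2),
                             setNames(integer(0), character(0))),
               "empty first-stage")
})

test_that("fragments of a synthetic genome rejoin their genome's bin", {
  comm <- generate_community(community_spec(
    n_genomes = 3, genome_length = 120000, n_samples = 2, seed = 19))
  lens <- contig_lengths(comm$contigs)
  n1 <- ceiling(0.7 * length(lens))
  stage1 <- sort(order(-lens, seq_along(lens))[seq_len(n1)])
  ids1 <- contig_ids(comm$contigs)[stage1]
  ids2 <- setdiff(contig_ids(comm$contigs), ids1)
  sig <- clr_transform(count_kmers(comm$contigs, "4mer"))
  truth1 <- factor(comm$gold[ids1])
  out <- assign_stage2(sig[ids2, , drop = FALSE], sig[ids1, , drop = FALSE],
                       setNames(as.integer(truth1), ids1))
  hit <- levels(truth1)[out] == comm$gold[ids2]
  expect_gte(mean(hit), 0.9)
})
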