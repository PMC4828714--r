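test_that("contingency tabulates by length, not by count", {
  assignment <- c(c1 = 1L, c2 = 2L, c3 = 2L)
  gold <- c(c1 = "g1", c2 = "g1", c3 = "g2")
  lengths <- c(c1 = 10000, c2 = 5000, c3 = 20000)
  ct <- binning_contingency(assignment, gold, lengths)
  expect_equal(ct$S, matrix(c(10000, 5000, 0, 20000), 2, 2,
                            dimnames = list(c("1", "2"), c("g1", "g2"))))
  expect_equal(unname(ct$genome_totals), c(15000, 20000))
  # an unbinned gold contig adds to genome totals only
  gold2 <- c(gold, c4 = "g2")
  ct2 <- binning_contingency(assignment, gold2, c(lengths, c4 = 7000))
  expect_equal(ct2$S, ct$S)
  expect_equal(unname(ct2$genome_totals["g2"]), 27000)
  # binned contigs missing from the gold standard are dropped with warning
  expect_warning(
    ct3 <- binning_contingency(c(assignment, cX = 1L), gold,
                               c(lengths, cX = 100)),
    "absent from the gold")
  expect_equal(ct3$S, ct$S)
})

test_that("the worked per-genome recall example reproduces", {
  S <- matrix(2125683, 1, 1, dimnames = list("23", "olsenella"))
  sc <- binning_scores(S, genome_totals = c(olsenella = 2162161))
  expect_equal(round(sc$per_genome$recall, 2), 98.31)
  expect_equal(round(sc$recall, 2), 98.31)
})

test_that("harmonic-mean F1 reproduces the published benchmark rows", {
  # (precision, recall) -> F1 to one decimal
  rows <- list(
    c(97.79, 97.79, 97.8),   # 10 genomes, default
    c(99.17, 98.45, 98.8),   # 10 genomes, one stage
    c(87.45, 90.54, 89.0),   # 100 genomes, default
    c(89.68, 94.09, 91.8),   # 100 genomes, 5p6mer + coverage
    c(88.97, 97.35, 93.0),   # 25 genomes, default
    c(95.87, 97.28, 96.6),   # 25 genomes, 4mer + coverage
    c(83.19, 88.76, 85.9),   # 64 genomes, default
    c(84.36, 92.85, 88.4),   # 64 genomes, 5p6mer + coverage
    c(86.72, 98.68, 92.3),   # infant gut, 4mer + coverage
    c(59.67, 97.40, 74.0))   # independent check: a competing tool's row
  for (r in rows)
    expect_equal(round(f1_score(r[1], r[2]), 1), r[3])
})

test_that("perfect clustering scores 100/100/100", {
  S <- diag(c(1e6, 2e6, 3e6))
  dimnames(S) <- list(1:3, paste0("g", 1:3))
  sc <- binning_scores(S, genome_totals = setNames(colSums(S), colnames(S)))
  expect_equal(sc$precision, 100)
  expect_equal(sc$recall, 100)
  expect_equal(sc$f1, 100)
})

test_that("score bounds and merge/split monotonicity hold on random tables", {
  withr::with_seed(123, {
    for (rep in 1:20) {
      m <- sample(2:6, 1); n <- sample(2:6, 1)
      S <- matrix(rpois(m * n, 2) * 1000, m, n,
                  dimnames = list(seq_len(m), paste0("g", seq_len(n))))
      S[rowSums(S) == 0, 1] <- 1000
      totals <- setNames(colSums(S) + rpois(n, 1) * 500, colnames(S))
      sc <- binning_scores(S, totals)
      expect_true(sc$precision >= 0 && sc$precision <= 100)
      expect_true(sc$recall >= 0 && sc$recall <= 100)
      expect_gte(sc$f1, min(sc$precision, sc$recall) - 1e-9)
      expect_lte(sc$f1, max(sc$precision, sc$recall) + 1e-9)
      # brute-force recomputation from first principles
      bf_p <- 100 * sum(apply(S, 1, max)) / sum(S)
      bf_r <- 100 * sum(apply(S, 2, max)) / sum(totals)
      expect_equal(sc$precision, bf_p)
      expect_equal(sc$recall, bf_r)
      # merging two pure clusters of different genomes never raises precision
      if (m >= 2) {
        pure <- rbind(S, 0)
        pure[m + 1, ] <- 0
        Sm <- S
        Sm[1, ] <- S[1, ] + S[2, ]
        Sm <- Sm[-2, , drop = FALSE]
        expect_lte(100 * sum(apply(Sm, 1, max)) / sum(Sm), bf_p + 1e-9)
      }
      # splitting a pure cluster in two never changes precision
      j <- which.max(S[1, ])
      Spure <- S
      Spure[1, ] <- 0
      Spure[1, j] <- S[1, j] + 1000
      p_before <- 100 * sum(apply(Spure, 1, max)) / sum(Spure)
      Ssplit <- rbind(Spure, 0)
      Ssplit[nrow(Ssplit), j] <- Spure[1, j] / 2
      Ssplit[1, j] <- Spure[1, j] / 2
      expect_equal(100 * sum(apply(Ssplit, 1, max)) / sum(Ssplit), p_before)
    }
  })
  expect_error(binning_scores(matrix(0, 1, 1), c(g = 0)), "zero total")
})

test_that("evaluation report writes and the file pipeline scores end to end", {
  dir <- withr::local_tempdir()
  seqs <- setNames(vapply(1:6, function(i) random_dna(1500, seed = 200 + i),
                          character(1)), paste0("ctg", 1:6))
  fa <- file.path(dir, "a.fasta")
  writeLines(unlist(lapply(names(seqs), function(i) c(paste0(">", i), seqs[[i]]))), fa)
  writeLines(c("contig_id\tcluster", paste0("ctg", 1:6, "\t", rep(1:2, each = 3))),
             file.path(dir, "bins.tsv"))
  writeLines(paste0("ctg", 1:6, "\t", rep(c("gA", "gB"), each = 3)),
             file.path(dir, "gold.tsv"))
  sc <- run_evaluation(file.path(dir, "bins.tsv"), file.path(dir, "gold.tsv"),
                       fa, out = file.path(dir, "report.tsv"))
  expect_equal(sc$precision, 100)
  expect_equal(sc$recall, 100)
  expect_true(file.exists(file.path(dir, "report.tsv")))
  expect_match(readLines(file.path(dir, "report.tsv"))[1], "F1=100")
  # disjoint ids error
  writeLines(c("contig_id\tcluster", "zzz\t1"), file.path(dir, "bad.tsv"))
  expect_error(run_evaluation(file.path(dir, "bad.tsv"),
                              file.path(dir, "gold.tsv"), fa),
               "no contig ids shared")
})
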