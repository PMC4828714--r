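#' Specify a synthetic metagenomic community
#'
#' Collects the parameters of the synthetic community generator. Each
#' genome is an independent random Markov chain of order `markov_order`,
#' giving genomes distinct oligonucleotide signatures of realistic
#' contrast; genomes are fragmented into lognormally sized contigs; per
#' sample, genome abundances follow either a power-law series (assigned to
#' genomes in an independent random order per sample) or a uniform draw,
#' and per-contig depths add lognormal noise around the genome abundance
#' (coefficient of variation 0.1). Each genome carries exactly one copy of
#' each of the 40 universal single-copy marker-gene families, placed on
#' random contigs.
#'
#' @param n_genomes Number of genomes (>= 2; default 10).
#' @param genome_length Genome length in bp (default 1e6).
#' @param markov_order Order of the per-genome Markov chain (default 3).
#' @param contig_meanlog,contig_sdlog Lognormal contig-length parameters
#'   (defaults `log(8000)` and 0.7; draws below `min_length` are
#'   rejected).
#' @param min_length Minimum contig length in bp (default 1000).
#' @param n_samples Number of sequencing libraries (default 4).
#' @param abundance Abundance model: `"power_law"` (default) or
#'   `"uniform"`.
#' @param depth_scale Mean depth scale of the most abundant genome
#'   (default 50).
#' @param depth_cv Lognormal per-contig depth noise, coefficient of
#'   variation (default 0.1).
#' @param seed Integer seed; the whole community is deterministic given
#'   the seed.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 10, genome_length = 1e6,
                           markov_order = 3, contig_meanlog = log(8000),
                           contig_sdlog = 0.7, min_length = 1000,
                           n_samples = 4,
                           abundance = c("power_law", "uniform"),
                           depth_scale = 50, depth_cv = 0.1, seed = 42) {
  abundance <- match.arg(abundance)
  if (n_genomes < 2) stop("need at least 2 genomes")
  if (min_length > genome_length) stop("min contig length exceeds genome length")
  structure(
    list(n_genomes = as.integer(n_genomes), genome_length = genome_length,
         markov_order = as.integer(markov_order),
         contig_meanlog = contig_meanlog, contig_sdlog = contig_sdlog,
         min_length = min_length, n_samples = as.integer(n_samples),
         abundance = abundance, depth_scale = depth_scale,
         depth_cv = depth_cv, seed = as.integer(seed)),
    class = "community_spec"
  )
}

#' Generate a synthetic metagenomic community
#'
#' Produces the four inputs of a binning run — contigs, a per-sample depth
#' table, a marker-gene annotation, and the gold-standard
#' contig-to-genome assignment — from a [community_spec()]. Fully
#' deterministic given the spec's seed.
#'
#' @param spec A [community_spec()].
#' @return A list of class `synthetic_community`: `contigs` (a
#'   [contig_set()]), `depths` (contig x sample matrix), `markers` (named
#'   list of family-id vectors), `gold` (named character vector), and
#'   `spec`.
#' @export
generate_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, {
    seqs <- character(0)
    gold <- character(0)
    markers <- list()
    depths <- NULL
    abund <- genome_abundances(spec)                # n_genomes x n_samples
    for (g in seq_len(spec$n_genomes)) {
      gid <- sprintf("genome_%02d", g)
      genome <- markov_genome(spec$genome_length, spec$markov_order)
      lens <- fragment_lengths(spec$genome_length, spec$contig_meanlog,
                               spec$contig_sdlog, spec$min_length)
      starts <- cumsum(c(1, lens[-length(lens)]))
      ids <- sprintf("%s_ctg%03d", gid, seq_along(lens))
      seqs[ids] <- substring(genome, starts, starts + lens - 1L)
      gold[ids] <- gid
      # one copy of each of the 40 single-copy families, on random contigs
      host <- sample(ids, length(marker_families()), replace = TRUE)
      for (i in seq_along(host))
        markers[[host[i]]] <- c(markers[[host[i]]], marker_families()[i])
      noise <- matrix(stats::rlnorm(length(ids) * spec$n_samples,
                                    -log(1 + spec$depth_cv^2) / 2,
                                    sqrt(log(1 + spec$depth_cv^2))),
                      length(ids), spec$n_samples)
      depths <- rbind(depths, noise * rep(abund[g, ], each = length(ids)))
    }
    rownames(depths) <- names(seqs)
    colnames(depths) <- sprintf("sample_%d", seq_len(spec$n_samples))
    list(contigs = contig_set(seqs, min_length = spec$min_length),
         depths = depths, markers = markers, gold = gold, spec = spec) |>
      structure(class = "synthetic_community")
  })
}

#' The 40 universal single-copy marker-gene family ids
#'
#' Family labels in the COG style used by marker annotations.
#'
#' @return Character vector of length 40.
#' @export
marker_families <- function() sprintf("COG%04d", 1:40)

#' Write a synthetic community to disk
#'
#' Writes the four files in exactly the formats the readers of this
#' package consume: `contigs.fasta`, `depth.tsv` (plain dialect),
#' `markers.tsv`, and `gold.tsv`.
#'
#' @param community A `synthetic_community` from [generate_community()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
write_community <- function(community, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  fa <- file.path(outdir, "contigs.fasta")
  Biostrings::writeXStringSet(community$contigs$seqs, fa)
  dp <- file.path(outdir, "depth.tsv")
  data.table::fwrite(
    data.frame(contig_id = rownames(community$depths), community$depths,
               check.names = FALSE),
    dp, sep = "\t")
  mk <- file.path(outdir, "markers.tsv")
  data.table::fwrite(
    data.frame(contig_id = names(community$markers),
               families = vapply(community$markers, paste,
                                 character(1L), collapse = ",")),
    mk, sep = "\t", col.names = FALSE)
  gd <- file.path(outdir, "gold.tsv")
  data.table::fwrite(
    data.frame(contig_id = names(community$gold),
               genome = unname(community$gold)),
    gd, sep = "\t", col.names = FALSE)
  invisible(c(fasta = fa, depth = dp, markers = mk, gold = gd))
}

# Simulate one genome from a random order-k Markov chain. The transition
# matrix rows are Dirichlet-like draws (normalized gamma), giving each
# genome its own oligonucleotide signature.
markov_genome <- function(length_bp, order) {
  bases <- c("A", "C", "G", "T")
  nstates <- 4L^order
  trans <- matrix(stats::rgamma(nstates * 4L, shape = 2), nstates, 4L)
  trans <- trans / rowSums(trans)
  cum <- t(apply(trans, 1L, cumsum))
  out <- integer(length_bp)
  out[seq_len(order)] <- sample.int(4L, order, replace = TRUE)
  state <- sum((out[seq_len(order)] - 1L) * 4L^((order - 1L):0)) + 1L
  u <- stats::runif(length_bp)
  for (i in (order + 1L):length_bp) {
    nxt <- 1L + (u[i] > cum[state, 1L]) + (u[i] > cum[state, 2L]) +
      (u[i] > cum[state, 3L])
    out[i] <- nxt
    state <- (state - 1L) %% (4L^(order - 1L)) * 4L + nxt
  }
  paste(bases[out], collapse = "")
}

# Lognormal fragment lengths covering a genome; draws below min_length are
# rejected; the tail fragment is attached to the last contig.
fragment_lengths <- function(total, meanlog, sdlog, min_length) {
  lens <- numeric(0)
  while (sum(lens) < total) {
    l <- round(stats::rlnorm(1L, meanlog, sdlog))
    if (l < min_length) next
    lens <- c(lens, l)
  }
  over <- sum(lens) - total
  lens[length(lens)] <- lens[length(lens)] - over
  if (lens[length(lens)] < min_length && length(lens) > 1L) {
    lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  as.integer(lens)
}

# Per-sample genome abundances under the spec's abundance model.
genome_abundances <- function(spec) {
  g <- spec$n_genomes
  vapply(seq_len(spec$n_samples), function(s) {
    if (spec$abundance == "power_law") {
      series <- spec$depth_scale * (seq_len(g))^(-0.75)
      series[sample.int(g)]      # independent rank order per sample
    } else {
      stats::runif(g, 0.1, 1) * spec$depth_scale
    }
  }, numeric(g))
}
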