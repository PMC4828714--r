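#' Count canonical k-mer occurrences
#'
#' Slides a window of each word size in the scheme along every sequence and
#' counts occurrences of each feature k-mer together with its reverse
#' complement (palindromic features are counted once). Windows containing
#' any letter outside A/C/G/T — in particular N — match no feature and are
#' skipped, which preserves strand invariance.
#'
#' @param seqs A `DNAStringSet`, a [contig_set()], or a character vector of
#'   DNA sequences (names become row names).
#' @param scheme A [kmer_scheme()] or a scheme name.
#' @return Integer matrix, one row per sequence, one column per feature
#'   k-mer in scheme order.
#' @examples
#' count_kmers(c(c1 = "AAAA", c2 = "ACGT"), "4mer")[, c("AAAA", "ACGT")]
#' @export
count_kmers <- function(seqs, scheme) {
  if (is.character(scheme)) scheme <- kmer_scheme(scheme)
  seqs <- as_dna(seqs)
  ks <- as.integer(names(scheme$features))
  if (length(seqs) && min(Biostrings::width(seqs)) < max(ks))
    stop("all sequences must be at least ", max(ks), " bp for scheme '",
         scheme$name, "' (shortest is ", min(Biostrings::width(seqs)), " bp)")
  blocks <- lapply(ks, function(k) {
    feats <- scheme$features[[as.character(k)]]
    raw <- Biostrings::oligonucleotideFrequency(seqs, width = k)
    rc <- revcomp(feats)
    counts <- raw[, feats, drop = FALSE]
    other <- raw[, rc, drop = FALSE]
    other[, rc == feats] <- 0L          # palindromes: do not double-count
    counts + other
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- names(seqs)
  out
}

#' Count the signature of a single sequence
#'
#' @param sequence A single DNA string over A/C/G/T/N.
#' @inheritParams count_kmers
#' @return Integer vector of feature counts, named by feature k-mer.
#' @export
count_signature <- function(sequence, scheme) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  drop(count_kmers(Biostrings::DNAStringSet(sequence), scheme))
}

#' Centered log-ratio transform of k-mer counts
#'
#' One pseudocount is added to every feature to eliminate zeros, counts are
#' normalized to relative frequencies, and each row is mapped to
#' `log(x / geometric_mean(x))`. Every output row sums to zero (within
#' floating-point tolerance), the defining property of the CLR.
#'
#' @param counts Non-negative count matrix (rows = sequences) or a single
#'   count vector.
#' @return Numeric matrix (or vector) of the same shape in CLR space.
#' @examples
#' clr_transform(c(3, 1))   # c(0.3466, -0.3466)
#' @export
clr_transform <- function(counts) {
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, nrow = 1L) else as.matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  lx <- log(m + 1) - log(rowSums(m + 1))   # log relative frequencies
  out <- lx - rowMeans(lx)
  dimnames(out) <- dimnames(m)
  if (vec) drop(out) else out
}

#' Centered log-ratio transform of depth profiles
#'
#' Depth rows are compositional across samples but may contain true zeros
#' (a genome absent from a library), so no pseudocount is used: the
#' geometric mean of each row is taken over its strictly positive entries
#' only, positive depths map to `log(depth / geometric_mean)`, and zero
#' depths map to 0 — the CLR value of a depth equal to the row geometric
#' mean, the least-informative finite encoding. A row of all zeros yields
#' an all-zero row with a warning. A single-sample table therefore
#' contributes a zero column.
#'
#' @param depths Non-negative numeric matrix, one row per contig, one
#'   column per sequencing library.
#' @return Numeric matrix of the same shape.
#' @examples
#' clr_coverage(matrix(c(2, 8), nrow = 1))   # c(-0.693, 0.693)
#' @export
clr_coverage <- function(depths) {
  m <- as.matrix(depths)
  if (!is.numeric(m)) stop("depths must be numeric")
  if (any(m < 0)) stop("depths must be non-negative")
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  pos <- m > 0
  npos <- rowSums(pos)
  if (any(npos == 0))
    warning(sum(npos == 0), " contig(s) have zero depth in every sample; ",
            "their coverage rows are all-zero")
  lg <- log(m)
  lg[!pos] <- 0
  gm <- ifelse(npos > 0, rowSums(lg) / pmax(npos, 1L), 0)
  out[pos] <- (lg - gm)[pos]
  out
}

#' Assemble the contig feature matrix
#'
#' Builds the CLR-transformed canonical k-mer signature block and, when a
#' depth table is supplied, appends the CLR-transformed coverage block
#' column-wise with unit weight. This matrix is the input to the 2-D
#' embedding.
#'
#' @param contigs A [contig_set()], `DNAStringSet`, or named character
#'   vector of sequences.
#' @param scheme A [kmer_scheme()] or scheme name (default `"4mer"`).
#' @param depths Optional depth matrix with one row per contig; row names
#'   (or row order) must cover all contigs.
#' @return Numeric matrix with one row per contig. Attribute `blocks`
#'   records the column spans of the `kmer` and `coverage` blocks.
#' @export
contig_features <- function(contigs, scheme = "4mer", depths = NULL) {
  if (is.character(scheme)) scheme <- kmer_scheme(scheme)
  seqs <- as_dna(contigs)
  kmer <- clr_transform(count_kmers(seqs, scheme))
  blocks <- list(kmer = seq_len(ncol(kmer)))
  out <- kmer
  if (!is.null(depths)) {
    depths <- match_depths(depths, names(seqs))
    cov <- clr_coverage(depths)
    blocks$coverage <- ncol(kmer) + seq_len(ncol(cov))
    out <- cbind(kmer, cov)
  }
  rownames(out) <- names(seqs)
  attr(out, "blocks") <- blocks
  attr(out, "scheme") <- scheme$name
  out
}

# Reorder a depth matrix to a given contig id order, failing loudly on
# missing contigs.
match_depths <- function(depths, ids) {
  m <- as.matrix(depths)
  if (is.null(rownames(m))) {
    if (nrow(m) != length(ids))
      stop("depth table has ", nrow(m), " rows but there are ",
           length(ids), " contigs, and it carries no contig ids")
    rownames(m) <- ids
    return(m)
  }
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stop("contigs missing from depth table: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L))
  m[ids, , drop = FALSE]
}

# Coerce the accepted sequence containers to a named DNAStringSet.
as_dna <- function(x) {
  if (inherits(x, "contig_set")) return(x$seqs)
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(x)
    names(out) <- names(x)
    return(out)
  }
  stop("cannot interpret object of class '", class(x)[1L], "' as sequences")
}
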