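#' Contig sets
#'
#' A `contig_set` is the universe of sequences being binned: an ordered,
#' uniquely named collection of uppercase DNA sequences over A/C/G/T/N, all
#' at least `min_length` bp long. Lowercase letters are uppercased and any
#' symbol outside A/C/G/T/N (IUPAC ambiguity codes included) is collapsed
#' to N during construction.
#'
#' @param seqs Named character vector or `DNAStringSet` of sequences.
#' @param min_length Minimum retained contig length in bp (default 1000);
#'   shorter records are dropped.
#' @return An object of class `contig_set`: list with `seqs` (a named
#'   `DNAStringSet`) and `min_length`.
#' @export
contig_set <- function(seqs, min_length = 1000) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs)) stop("seqs must be character or DNAStringSet")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every sequence must be named with a contig id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate contig id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  clean <- gsub("[^ACGTN]", "N", toupper(seqs))
  keep <- nchar(clean) >= min_length
  if (!any(keep))
    warning("no contigs of length >= ", min_length, " bp retained")
  structure(
    list(seqs = Biostrings::DNAStringSet(stats::setNames(clean[keep], ids[keep])),
         min_length = min_length),
    class = "contig_set"
  )
}

#' @export
print.contig_set <- function(x, ...) {
  w <- Biostrings::width(x$seqs)
  cat("contig_set: ", length(w), " contigs, ",
      format(sum(w), big.mark = ","), " bp total (min length ",
      x$min_length, " bp)\n", sep = "")
  invisible(x)
}

#' @export
length.contig_set <- function(x) length(x$seqs)

#' @export
`[.contig_set` <- function(x, i) {
  structure(list(seqs = x$seqs[i], min_length = x$min_length),
            class = "contig_set")
}

#' Contig ids of a contig set
#' @param x A `contig_set`.
#' @return Character vector of contig ids, in set order.
#' @export
contig_ids <- function(x) names(x$seqs)

#' Contig lengths of a contig set
#' @param x A `contig_set`.
#' @return Named integer vector of contig lengths in bp.
#' @export
contig_lengths <- function(x) stats::setNames(Biostrings::width(x$seqs), names(x$seqs))

#' Read assembled contigs from FASTA
#'
#' Reads a (plain or gzipped) FASTA file, tokenizes contig ids at the first
#' whitespace of each header (matching the behavior of common mappers and
#' depth tables), normalizes sequences to uppercase A/C/G/T/N, and drops
#' records shorter than `min_length`.
#'
#' @param path Path to a FASTA file.
#' @param min_length Minimum retained contig length in bp (default 1000).
#' @return A [contig_set()] with records in file order.
#' @export
read_contigs <- function(path, min_length = 1000) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  contig_set(stats::setNames(as.character(raw), ids), min_length = min_length)
}

#' Read a per-sample contig depth table
#'
#' Parses a tab-separated depth table with a header line. The dialect is
#' explicit, never sniffed:
#'
#' * `"metabat"` — the `jgi_summarize_bam_contig_depths` layout
#'   (`contigName`, `contigLen`, `totalAvgDepth`, then per-library mean
#'   depth and variance column pairs); only the per-library mean-depth
#'   columns are kept.
#' * `"concoct"` / `"plain"` — contig id first, then one numeric depth
#'   column per library; all numeric columns are kept.
#'
#' @param path Path to the TSV file.
#' @param dialect One of `"plain"`, `"metabat"`, `"concoct"`.
#' @return Numeric matrix of mean depths, contig ids as row names, one
#'   column per library.
#' @export
read_depth_table <- function(path, dialect = c("plain", "metabat", "concoct")) {
  dialect <- match.arg(dialect)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          check.names = FALSE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("depth table needs a contig id and >= 1 depth column")
  ids <- as.character(dt[[1L]])
  if (dialect == "metabat") {
    if (ncol(dt) < 4L)
      stop("metabat depth table needs at least 4 columns ",
           "(contigName, contigLen, totalAvgDepth, <lib>.bam, ...)")
    vals <- dt[, -(1:3), drop = FALSE]
    vals <- vals[, !grepl("-var$", names(vals)), drop = FALSE]
  } else {
    vals <- dt[, -1L, drop = FALSE]
  }
  vals <- vals[, vapply(vals, is.numeric, logical(1L)), drop = FALSE]
  if (ncol(vals) == 0L) stop("no numeric depth columns found in ", path)
  m <- as.matrix(vals)
  if (any(m < 0)) stop("negative depth values in ", path)
  rownames(m) <- ids
  m
}

#' Read a contig-to-marker-gene annotation table
#'
#' Two tab-separated columns, no header: contig id, then a comma-separated
#' list of single-copy marker-gene family ids carried by that contig (a
#' family may appear more than once). Contigs absent from the table carry
#' no markers.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping contig id to a character vector of family
#'   ids (with repeats).
#' @export
read_marker_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 2L) stop("marker table needs two columns: contig id, families")
  fams <- strsplit(dt[[2L]], ",", fixed = TRUE)
  fams <- lapply(fams, function(f) f[nzchar(f)])
  stats::setNames(fams, dt[[1L]])
}

#' Read a gold-standard contig-to-genome assignment table
#'
#' Two tab-separated columns, no header: contig id, genome id (the layout
#' of `scaffolds_to_bin` truth tables).
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping contig id to genome id.
#' @export
read_gold_standard <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 2L) stop("gold standard needs two columns: contig id, genome id")
  dup <- unique(dt[[1L]][duplicated(dt[[1L]])])
  if (length(dup))
    stop("contig(s) assigned to more than one genome: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  stats::setNames(dt[[2L]], dt[[1L]])
}

#' Write genome bins and companion tables
#'
#' Writes one `Cluster.<i>.fasta` per non-empty bin containing exactly its
#' member contigs, a two-column `bins.tsv` (contig id, cluster), and — when
#' 2-D coordinates are available — a `coordinates.tsv` (contig id, x, y,
#' cluster) for scatter plotting.
#'
#' @param assignment A named integer vector mapping contig id to cluster,
#'   or a binning result from [bin_contigs()].
#' @param contigs The [contig_set()] the assignment refers to.
#' @param outdir Output directory (created if absent).
#' @param coords Optional matrix/data frame of 2-D coordinates with contig
#'   ids as row names (taken from a binning result automatically).
#' @return Invisibly, the paths of the files written.
#' @export
write_bins <- function(assignment, contigs, outdir, coords = NULL) {
  if (inherits(assignment, "binning")) {
    if (is.null(coords)) coords <- assignment$coords
    assignment <- binned_clusters(assignment)
  }
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  missing <- setdiff(names(assignment), contig_ids(contigs))
  if (length(missing))
    stop("assigned contigs absent from contig set: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  paths <- character(0)
  for (cl in sort(unique(assignment))) {
    members <- names(assignment)[assignment == cl]
    if (length(members) == 0L) next
    p <- file.path(outdir, sprintf("Cluster.%d.fasta", cl))
    Biostrings::writeXStringSet(contigs$seqs[members], p)
    paths <- c(paths, p)
  }
  tab <- file.path(outdir, "bins.tsv")
  data.table::fwrite(
    data.frame(contig_id = names(assignment), cluster = unname(assignment)),
    tab, sep = "\t")
  paths <- c(paths, tab)
  if (!is.null(coords)) {
    co <- as.matrix(coords[, 1:2, drop = FALSE])
    ids <- rownames(co)
    cp <- file.path(outdir, "coordinates.tsv")
    data.table::fwrite(
      data.frame(contig_id = ids, x = co[, 1L], y = co[, 2L],
                 cluster = unname(assignment[ids])),
      cp, sep = "\t")
    paths <- c(paths, cp)
  }
  invisible(paths)
}

#' Per-bin summary statistics
#'
#' One row per bin, sorted by cluster id, reporting total assembled size
#' (`WholeGenome`, bp), `N50` (the largest length L such that member
#' contigs of length >= L sum to at least half the bin total), the number
#' of member contigs (`NoOfCtg`), and the number of distinct single-copy
#' marker-gene families present (`Cogs`; 0 when no annotation is given).
#'
#' @inheritParams write_bins
#' @param markers Optional marker annotation (named list, as from
#'   [read_marker_table()]).
#' @return A data frame with columns `cluster`, `WholeGenome`, `N50`,
#'   `NoOfCtg`, `Cogs`.
#' @export
bin_summary <- function(assignment, contigs, markers = NULL) {
  if (inherits(assignment, "binning")) assignment <- binned_clusters(assignment)
  lens <- contig_lengths(contigs)[names(assignment)]
  out <- lapply(sort(unique(assignment)), function(cl) {
    members <- names(assignment)[assignment == cl]
    fams <- if (is.null(markers)) character(0) else
      unlist(markers[intersect(members, names(markers))], use.names = FALSE)
    data.frame(cluster = cl,
               WholeGenome = sum(lens[members]),
               N50 = n50(lens[members]),
               NoOfCtg = length(members),
               Cogs = length(unique(fams)))
  })
  do.call(rbind, out)
}

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L together comprise
#' at least half the total length. Invariant to the order of the input.
#'
#' @param lengths Numeric vector of contig lengths in bp.
#' @return The N50 in bp.
#' @examples
#' n50(c(5, 4, 3, 2, 1) * 1000)  # 4000
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}
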