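#' K-mer signature schemes
#'
#' A signature scheme fixes the ordered list of k-mer features used to build
#' genomic signatures. Features are *canonical* k-mers: each k-mer is
#' represented by the lexicographically smaller of itself and its reverse
#' complement, so that signatures are strand-invariant. Three schemes are
#' supported:
#'
#' * `"4mer"`  — 136 canonical tetranucleotides,
#' * `"5mer"`  — 512 canonical pentanucleotides,
#' * `"5p6mer"` — the 512 canonical pentanucleotides plus the 64
#'   palindromic hexanucleotides (hexamers equal to their own reverse
#'   complement), 576 features in total. `"56mer"` is accepted as an alias.
#'
#' @param name Scheme name: `"4mer"`, `"5mer"`, or `"5p6mer"` (alias
#'   `"56mer"`).
#' @return An object of class `kmer_scheme`: a list with elements `name`,
#'   `features` (a named list, one character vector of feature k-mers per
#'   word size), and `dims` (total number of features).
#' @examples
#' sc <- kmer_scheme("4mer")
#' sc$dims              # 136
#' head(sc$features$`4`)
#' @export
kmer_scheme <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    stop("scheme name must be a single string")
  if (name == "56mer") name <- "5p6mer"
  features <- switch(name,
    "4mer"   = list(`4` = canonical_kmers(4L)),
    "5mer"   = list(`5` = canonical_kmers(5L)),
    "5p6mer" = list(`5` = canonical_kmers(5L), `6` = palindromic_kmers(6L)),
    stop("unknown k-mer scheme: '", name,
         "' (expected one of '4mer', '5mer', '5p6mer')")
  )
  structure(
    list(name = name, features = features,
         dims = sum(lengths(features))),
    class = "kmer_scheme"
  )
}

#' @export
print.kmer_scheme <- function(x, ...) {
  cat("k-mer scheme '", x$name, "': ", x$dims, " features (",
      paste(sprintf("k=%s: %d", names(x$features), lengths(x$features)),
            collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Enumerate canonical k-mers
#'
#' All DNA words of length `k` over A/C/G/T, collapsed to canonical form
#' (the lexicographic minimum of a word and its reverse complement) and
#' returned sorted. For even `k` this includes the palindromes, counted
#' once.
#'
#' @param k Word size.
#' @return Sorted character vector of canonical k-mers.
#' @export
canonical_kmers <- function(k) {
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  sort(unique(pmin(words, revcomp(words))))
}

#' Enumerate palindromic k-mers
#'
#' DNA words equal to their own reverse complement. Only even word sizes
#' have palindromes.
#'
#' @param k Word size (even).
#' @return Sorted character vector of palindromic k-mers.
#' @export
palindromic_kmers <- function(k) {
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  sort(words[words == revcomp(words)])
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
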