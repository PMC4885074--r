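#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed. `N` maps to `N`. Vectorised over the
#' input; applying it twice returns the original sequence.
#'
#' @param sequence Character vector of DNA sequences over `{A,C,G,T,N}`
#'   (case-insensitive; returned uppercase).
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("ACGT")  # palindromic
#' reverse_complement("AAAA")
#' @export
reverse_complement <- function(sequence) {
  up <- .validate_dna(sequence)
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1L),
         USE.NAMES = FALSE)
}

#' Extract k-mers from a DNA sequence
#'
#' Slides a window of length `k` along one sequence with the given step and
#' returns the k-mers in order, with multiplicity. Windows containing any
#' non-`ACGT` base (i.e. `N`) are omitted. A sequence shorter than `k`
#' yields an empty vector.
#'
#' @param sequence A single DNA string.
#' @param k Window length, integer >= 1.
#' @param step Step size between window starts (default 1).
#' @return Character vector of k-mers (possibly empty).
#' @examples
#' extract_kmers("ACGTACGT", k = 4)
#' extract_kmers("ACNGT", k = 2)  # windows overlapping the N are dropped
#' @export
extract_kmers <- function(sequence, k, step = 1L) {
  stopifnot(length(sequence) == 1L, k >= 1L, step >= 1L)
  up <- .validate_dna(sequence)
  n <- nchar(up)
  if (n < k) return(character(0L))
  starts <- seq.int(1L, n - k + 1L, by = step)
  kms <- substring(up, starts, starts + k - 1L)
  if (grepl("N", up, fixed = TRUE)) {
    kms <- kms[!grepl("N", kms, fixed = TRUE)]
  }
  kms
}

#' Decompose a genome into a k-mer profile
#'
#' Builds the k-mer decomposition used throughout the package: the set of
#' distinct k-mers with their occurrence counts, plus the total number of
#' valid windows. Query profiles use the forward strand only; reference
#' profiles include the reverse complement as well, which makes them
#' strand-symmetric. Windows containing `N` are excluded on both strands.
#'
#' @param sequence A single DNA string of length >= `k`.
#' @param k k-mer length (default 16).
#' @param strands `"forward"` for query profiles, `"both"` for reference
#'   profiles.
#' @param id Optional record id, used in error messages and kept on the
#'   profile.
#' @return An object of class `kmer_profile`: a list with elements `k`,
#'   `strands`, `id`, `kmers` (data frame of `kmer`, `count`), `unique_count`
#'   and `total_count`.
#' @examples
#' kmer_profile("ACGTACGT", k = 4, strands = "forward")  # 4 unique, 5 total
#' kmer_profile("ACGTACGT", k = 4, strands = "both")     # 4 unique, 10 total
#' @export
kmer_profile <- function(sequence, k = 16L, strands = c("forward", "both"),
                         id = NULL) {
  strands <- match.arg(strands)
  stopifnot(length(sequence) == 1L, k >= 1L)
  up <- .validate_dna(sequence, id)
  if (nchar(up) < k) {
    stop("sequence ", id %||% "", " has length ", nchar(up),
         " < k = ", k, "; no profile can be built", call. = FALSE)
  }
  kms <- extract_kmers(up, k)
  if (strands == "both") {
    kms <- c(kms, extract_kmers(reverse_complement(up), k))
  }
  if (length(kms) == 0L) {
    stop("sequence ", id %||% "", " has no valid (N-free) ", k,
         "-mer window; profile unusable", call. = FALSE)
  }
  dt <- data.table::data.table(kmer = kms)[, list(count = .N), by = "kmer"]
  data.table::setkey(dt, kmer)
  structure(
    list(k = as.integer(k), strands = strands, id = id,
         kmers = dt,
         unique_count = nrow(dt),
         total_count = length(kms)),
    class = "kmer_profile"
  )
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("<kmer_profile> k=", x$k, " strands=", x$strands,
      if (!is.null(x$id)) paste0(" id=", x$id),
      ": ", x$unique_count, " unique / ", x$total_count, " total k-mers\n",
      sep = "")
  invisible(x)
}

# reference (both-strand) profiles for every record of a corpus, as a named
# list; shared by database construction, clustering and cross-validation so
# profiles are computed once per record
.reference_profiles <- function(corpus, k) {
  p <- lapply(seq_len(nrow(corpus)), function(i) {
    kmer_profile(corpus$sequence[i], k = k, strands = "both",
                 id = corpus$id[i])
  })
  names(p) <- corpus$id
  p
}

.query_profiles <- function(corpus, k) {
  p <- lapply(seq_len(nrow(corpus)), function(i) {
    kmer_profile(corpus$sequence[i], k = k, strands = "forward",
                 id = corpus$id[i])
  })
  names(p) <- corpus$id
  p
}
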