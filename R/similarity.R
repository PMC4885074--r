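#' K-mer similarity statistics
#'
#' Scalar (vectorised) building blocks of the per-reference similarity
#' measures. `S` is the number of distinct k-mers shared between query and
#' reference (the reference set includes both strands); `n_hits` is the sum
#' of `S` over all references hit by one query.
#'
#' * `kmer_expectation()`: expected score for reference *i* under a
#'   size-proportional null, `E = n_hits * lu / lu_tot`.
#' * `kmer_zscore()`: Poisson-style standardisation
#'   `z = (S - E) / sqrt(S + E + eta)`.
#' * `kmer_pvalues()`: two-sided normal p-value of `z` with Bonferroni
#'   correction by the number of references, capped at 1.
#' * `frac_q()`: `S / (q_unique + eta)` -- fraction of the query's distinct
#'   k-mers found in the reference.
#' * `frac_d()`: `S / (lu + eta)` -- fraction of the reference's distinct
#'   (both-strand) k-mers found in the query; lies in roughly `[0.5, 1]`
#'   for identical sequences because the denominator counts both strands.
#' * `kmer_coverage()`: `2 * q_matched / (l_total + eta)` where `q_matched`
#'   counts query k-mer occurrences (with multiplicity) matching the
#'   reference and `l_total` is the reference's multiplicity-inclusive
#'   k-mer count over both strands; can exceed 1 for repetitive queries.
#'
#' @param n_hits Sum of scores over all references for one query.
#' @param lu Reference unique k-mer count (both strands).
#' @param lu_tot Sum of `lu` over the database.
#' @param S Shared distinct k-mer count.
#' @param E Expected score.
#' @param eta Pseudocount avoiding division by zero (default 0.001).
#' @param z z-score.
#' @param n_ref Number of references in the database (Bonferroni factor).
#' @param q_unique Query unique k-mer count (forward strand).
#' @param q_matched Multiplicity-weighted matched query k-mer count.
#' @param l_total Reference total k-mer count over both strands.
#' @name similarity-measures
NULL

#' @rdname similarity-measures
#' @export
kmer_expectation <- function(n_hits, lu, lu_tot) {
  stopifnot(all(lu_tot > 0))
  # counts can exceed .Machine$integer.max when multiplied: work in doubles
  as.numeric(n_hits) * as.numeric(lu) / as.numeric(lu_tot)
}

#' @rdname similarity-measures
#' @export
kmer_zscore <- function(S, E, eta = 0.001) {
  (S - E) / sqrt(S + E + eta)
}

#' @rdname similarity-measures
#' @return `kmer_pvalues()` returns a tibble with columns `p` and `p_corr`.
#' @export
kmer_pvalues <- function(z, n_ref) {
  stopifnot(all(n_ref >= 1))
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(p = p, p_corr = pmin(1, p * n_ref))
}

#' @rdname similarity-measures
#' @export
frac_q <- function(S, q_unique, eta = 0.001) {
  stopifnot(all(q_unique >= 1))
  S / (q_unique + eta)
}

#' @rdname similarity-measures
#' @export
frac_d <- function(S, lu, eta = 0.001) {
  stopifnot(all(lu >= 1))
  S / (lu + eta)
}

#' @rdname similarity-measures
#' @export
kmer_coverage <- function(q_matched, l_total, eta = 0.001) {
  stopifnot(all(l_total >= 1))
  2 * q_matched / (l_total + eta)
}

#' Score queries against a reference database
#'
#' For each query genome, computes every similarity measure against every
#' reference sharing at least one k-mer: the raw score `S` (distinct shared
#' k-mers), expectation `E`, z-score, Bonferroni-corrected p-value, `frac_q`,
#' `frac_d` and `coverage`. References sharing no k-mer with the query are
#' omitted. Hits are sorted per query by coverage (descending), then `S`
#' (descending), then reference id -- a total, deterministic order that all
#' downstream selection criteria inherit.
#'
#' @param queries A data frame with columns `id` and `sequence`, or a
#'   (named) character vector of sequences.
#' @param db A `host_db` from [build_host_db()].
#' @param eta Pseudocount (default 0.001).
#' @param significance Corrected-p-value cutoff marking significant hits
#'   (default 0.05).
#' @return A tibble with one row per (query, reference) hit: `query_id`,
#'   `ref_id`, `host_genus`, `host_species`, `S`, `q_matched`, `E`, `z`,
#'   `p`, `p_corr`, `frac_q`, `frac_d`, `coverage`, `q_unique`, `n_hits`,
#'   `significant`. Queries with no hit contribute no rows.
#' @examples
#' corpus <- simulate_phage_corpus(n_hosts = 2, phages_per_host = 2,
#'                                 genome_length = 2000, seed = 1)
#' db <- build_host_db(corpus, k = 16)
#' hits <- score_query(corpus[1, ], db)
#' head(hits)
#' @export
score_query <- function(queries, db, eta = 0.001, significance = 0.05) {
  stopifnot(inherits(db, "host_db"))
  queries <- .as_corpus(queries, "queries")
  profiles <- .query_profiles(queries, db$k)
  out <- lapply(queries$id, function(qid) {
    .score_one(profiles[[qid]], db, eta = eta, significance = significance)
  })
  dplyr::bind_rows(out)
}

# score one precomputed forward-strand query profile against db
.score_one <- function(qprof, db, eta = 0.001, significance = 0.05) {
  if (qprof$k != db$k) {
    stop("query profile k (", qprof$k, ") does not match database k (",
         db$k, ")", call. = FALSE)
  }
  empty <- tibble::tibble(
    query_id = character(), ref_id = character(),
    host_genus = character(), host_species = character(),
    S = integer(), q_matched = integer(), E = double(), z = double(),
    p = double(), p_corr = double(), frac_q = double(), frac_d = double(),
    coverage = double(), q_unique = integer(), n_hits = integer(),
    significant = logical()
  )
  m <- db$index[qprof$kmers, on = "kmer", nomatch = NULL]
  if (nrow(m) == 0L) return(empty)
  agg <- m[, list(S = .N, q_matched = sum(count)), by = "ref_id"]
  n_hits <- sum(agg$S)
  h <- dplyr::inner_join(tibble::as_tibble(agg), db$entries,
                         by = c(ref_id = "id"))
  pv <- kmer_pvalues(kmer_zscore(h$S, kmer_expectation(n_hits, h$lu, db$Lu_tot),
                                 eta),
                     db$Nref)
  h <- dplyr::mutate(
    h,
    query_id = qprof$id %||% "query",
    E = kmer_expectation(n_hits, .data$lu, db$Lu_tot),
    z = kmer_zscore(.data$S, .data$E, eta),
    p = pv$p, p_corr = pv$p_corr,
    frac_q = frac_q(.data$S, qprof$unique_count, eta),
    frac_d = frac_d(.data$S, .data$lu, eta),
    coverage = kmer_coverage(.data$q_matched, .data$l_total, eta),
    q_unique = qprof$unique_count,
    n_hits = n_hits,
    significant = .data$p_corr < significance
  )
  h <- h[order(-h$coverage, -h$S, h$ref_id, method = "radix"), ]
  dplyr::select(h, dplyr::all_of(names(empty)))
}
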