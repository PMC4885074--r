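#' Host-selection criteria
#'
#' Turn one query's significant-hit list into a single host call. All four
#' criteria expect the hit tibble produced by [score_query()] (already in
#' the canonical coverage-descending order) and operate on the host label
#' of the requested taxonomic level.
#'
#' * Criterion 1: host of the hit with the highest coverage.
#' * Criterion 2: most abundant host among the `top_n` highest-coverage
#'   hits; a tie goes to the tied host whose best hit has the highest
#'   coverage.
#' * Criterion 3: most abundant host among hits with
#'   `coverage >= f * coverage1`; `f = 1` degenerates to criterion 1 and
#'   `f = 0` to a majority vote over all significant hits. Ties as in
#'   criterion 2.
#' * Criterion 4: per hit, `score = (coverage / coverage1)^alpha`; scores
#'   are summed per host and the top-scoring host wins. Large `alpha`
#'   approaches criterion 1. Ties as in criterion 2, then lexicographic.
#'
#' @param hits Tibble of significant hits for one query, sorted by
#'   coverage descending (as returned by [score_query()]).
#' @param level `"genus"` or `"species"`; selects the host label column.
#' @param top_n Number of top hits considered by criterion 2 (default 10;
#'   fewer hits than `top_n` means all of them).
#' @param f Coverage-threshold fraction for criterion 3, in `[0, 1]`.
#' @param alpha Exponent for criterion 4, > 0.
#' @return `criterion1()`--`criterion3()` return the winning host label
#'   (length-1 character). `criterion4()` returns a tibble of per-host
#'   summed scores (`host`, `score`, `best_coverage`), best first.
#' @name selection-criteria
NULL

.hit_hosts <- function(hits, level) {
  if (level == "genus") hits$host_genus else hits$host_species
}

# majority vote with the published tie rule: most abundant host; among tied
# hosts the one whose best hit has the highest coverage; then lexicographic
.majority_host <- function(hosts, coverages) {
  tab <- tibble::tibble(host = hosts, coverage = coverages) |>
    dplyr::group_by(.data$host) |>
    dplyr::summarise(n = dplyr::n(), best = max(.data$coverage),
                     .groups = "drop")
  tab <- tab[order(-tab$n, -tab$best, tab$host, method = "radix"), ]
  list(host = tab$host[1L], score = tab$n[1L])
}

#' @rdname selection-criteria
#' @export
criterion1 <- function(hits, level = c("genus", "species")) {
  level <- match.arg(level)
  stopifnot(nrow(hits) >= 1L)
  .hit_hosts(hits, level)[1L]
}

#' @rdname selection-criteria
#' @export
criterion2 <- function(hits, level = c("genus", "species"), top_n = 10L) {
  level <- match.arg(level)
  stopifnot(nrow(hits) >= 1L, top_n >= 1L)
  top <- hits[seq_len(min(top_n, nrow(hits))), ]
  .majority_host(.hit_hosts(top, level), top$coverage)$host
}

#' @rdname selection-criteria
#' @export
criterion3 <- function(hits, level = c("genus", "species"), f = 0.8) {
  level <- match.arg(level)
  stopifnot(nrow(hits) >= 1L, f >= 0, f <= 1)
  thr <- f * max(hits$coverage)
  elig <- hits[hits$coverage >= thr, ]   # inclusive: f = 1 reduces to criterion 1
  .majority_host(.hit_hosts(elig, level), elig$coverage)$host
}

#' @rdname selection-criteria
#' @export
criterion4 <- function(hits, level = c("genus", "species"), alpha = 6) {
  level <- match.arg(level)
  stopifnot(nrow(hits) >= 1L, alpha > 0)
  cov1 <- max(hits$coverage)
  tab <- tibble::tibble(host = .hit_hosts(hits, level),
                        score = (hits$coverage / cov1)^alpha,
                        coverage = hits$coverage) |>
    dplyr::group_by(.data$host) |>
    dplyr::summarise(score = sum(.data$score), best_coverage = max(.data$coverage),
                     .groups = "drop")
  tab[order(-tab$score, -tab$best_coverage, tab$host, method = "radix"), ]
}

#' Select a host from a significant-hit list
#'
#' Applies one of the four selection criteria (see
#' [selection-criteria][criterion1]) and returns the chosen host with its
#' criterion score (top coverage for criterion 1, vote count for criteria 2
#' and 3, summed normalised coverage score for criterion 4).
#'
#' @inheritParams selection-criteria
#' @param criterion Selection criterion, 1-4 (default 4, the deployed
#'   method with `alpha = 6`).
#' @return A list with elements `host` and `score`.
#' @export
select_host <- function(hits, criterion = 4L, level = c("genus", "species"),
                        f = 0.8, alpha = 6, top_n = 10L) {
  level <- match.arg(level)
  stopifnot(criterion %in% 1:4, nrow(hits) >= 1L)
  switch(
    as.character(criterion),
    "1" = list(host = criterion1(hits, level), score = max(hits$coverage)),
    "2" = {
      top <- hits[seq_len(min(top_n, nrow(hits))), ]
      .majority_host(.hit_hosts(top, level), top$coverage)
    },
    "3" = {
      thr <- f * max(hits$coverage)
      elig <- hits[hits$coverage >= thr, ]
      .majority_host(.hit_hosts(elig, level), elig$coverage)
    },
    "4" = {
      tab <- criterion4(hits, level, alpha)
      list(host = tab$host[1L], score = tab$score[1L])
    }
  )
}

# coverage-based confidence tier of a prediction
.assign_tier <- function(top_coverage, reliable_threshold = 0.1,
                         high_confidence_threshold = 0.8) {
  dplyr::case_when(
    is.na(top_coverage) ~ "no-prediction",
    top_coverage > high_confidence_threshold ~ "highly-reliable",
    top_coverage > reliable_threshold ~ "reliable",
    TRUE ~ "poorly-reliable"
  )
}

#' Predict the bacterial host of phage genomes
#'
#' End-to-end prediction: scores each query against the reference database,
#' keeps the significant hits (Bonferroni-corrected p below
#' `significance`), applies the configured selection criterion, and assigns
#' a confidence tier from the best hit's coverage: `> 0.8` highly-reliable,
#' `> 0.1` reliable, otherwise poorly-reliable; a query with no significant
#' hit gets tier `no-prediction` and an `NA` host.
#'
#' @inheritParams score_query
#' @inheritParams select_host
#' @param reliable_threshold Coverage above which a prediction is
#'   considered reliable (default 0.1).
#' @param high_confidence_threshold Coverage above which a prediction is
#'   considered highly reliable (default 0.8).
#' @return A tibble with one row per query: `query_id`, `level`, `host`,
#'   `criterion_score`, `top_coverage`, `best_p_corr`, `n_significant`,
#'   `tier`.
#' @examples
#' corpus <- simulate_phage_corpus(n_hosts = 3, phages_per_host = 3,
#'                                 genome_length = 3000, seed = 2)
#' db <- build_host_db(corpus, k = 16)
#' predict_host(corpus[1:3, ], db)
#' @export
predict_host <- function(queries, db, criterion = 4L, f = 0.8, alpha = 6,
                         top_n = 10L, eta = 0.001, significance = 0.05,
                         reliable_threshold = 0.1,
                         high_confidence_threshold = 0.8) {
  stopifnot(inherits(db, "host_db"))
  queries <- .as_corpus(queries, "queries")
  profiles <- .query_profiles(queries, db$k)
  rows <- lapply(queries$id, function(qid) {
    hits <- .score_one(profiles[[qid]], db, eta = eta,
                       significance = significance)
    .predict_from_hits(qid, hits, db$level, criterion, f, alpha, top_n,
                       reliable_threshold, high_confidence_threshold)
  })
  dplyr::bind_rows(rows)
}

.predict_from_hits <- function(qid, hits, level, criterion, f, alpha, top_n,
                               reliable_threshold, high_confidence_threshold) {
  sig <- hits[which(hits$significant), ]
  if (nrow(sig) == 0L) {
    return(tibble::tibble(
      query_id = qid, level = level, host = NA_character_,
      criterion_score = NA_real_, top_coverage = NA_real_,
      best_p_corr = NA_real_, n_significant = 0L,
      tier = "no-prediction"
    ))
  }
  sel <- select_host(sig, criterion = criterion, level = level, f = f,
                     alpha = alpha, top_n = top_n)
  tibble::tibble(
    query_id = qid, level = level, host = sel$host,
    criterion_score = as.numeric(sel$score),
    top_coverage = sig$coverage[1L],
    best_p_corr = sig$p_corr[1L],
    n_significant = nrow(sig),
    tier = .assign_tier(sig$coverage[1L], reliable_threshold,
                        high_confidence_threshold)
  )
}
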