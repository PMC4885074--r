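#' Hobohm-1 redundancy clustering of a phage corpus
#'
#' Greedy single-pass redundancy reduction on k-mer similarity. Records are
#' visited in a seeded random order; the first becomes a seed, and each
#' subsequent record is compared (by `frac_q`, the fraction of its distinct
#' forward-strand k-mers found in a seed's both-strand k-mer set) against
#' every existing seed. If its best `frac_q` exceeds `threshold` it joins
#' the most similar seed's cluster, otherwise it founds a new seed. The
#' result depends on the visit order, so `shuffle_seed` is recorded on the
#' output.
#'
#' @param corpus Data frame with columns `id`, `sequence`.
#' @param k k-mer length (default 16).
#' @param threshold `frac_q` similarity above which a record is considered
#'   redundant with a seed (default 0.7).
#' @param shuffle_seed Integer seed for the visit-order shuffle.
#' @param eta Pseudocount used inside `frac_q`.
#' @param direction Which of the two genomes acts as the query in the
#'   `frac_q` comparison: the candidate record (`"member_query"`, default)
#'   or the seed (`"seed_query"`). `frac_q` is asymmetric in genome length,
#'   so the direction matters for corpora of uneven genome sizes.
#' @return A tibble with one row per record: `id`, `seed_id` (cluster
#'   representative; equals `id` for seeds), `is_seed`, `fracq_to_seed`
#'   (`NA` for seeds). Attributes `threshold`, `shuffle_seed` and `k`
#'   record the clustering parameters.
#' @examples
#' corpus <- simulate_phage_corpus(n_hosts = 2, phages_per_host = 3,
#'                                 genome_length = 3000,
#'                                 signature_fraction = 1, snp_rate = 0,
#'                                 mosaic_swap_rate = 0, seed = 5)
#' cl <- hobohm_cluster(corpus, threshold = 0.7, shuffle_seed = 1)
#' table(cl$seed_id)
#' @export
hobohm_cluster <- function(corpus, k = 16L, threshold = 0.7, shuffle_seed = 1L,
                           eta = 0.001,
                           direction = c("member_query", "seed_query")) {
  direction <- match.arg(direction)
  corpus <- .as_corpus(corpus, "corpus")
  n <- nrow(corpus)
  stopifnot(n >= 1L)
  visit <- withr::with_seed(shuffle_seed, sample.int(n))
  qprof <- .query_profiles(corpus, k)
  rprof <- .reference_profiles(corpus, k)

  seed_ids <- character(0L)
  res_seed <- character(n)
  res_frac <- rep(NA_real_, n)

  # profiles are keyed on kmer, so each seed comparison is one sorted join
  for (i in visit) {
    id <- corpus$id[i]
    best_seed <- NA_character_
    best_frac <- -Inf
    if (length(seed_ids) > 0L) {
      fr <- if (direction == "member_query") {
        qdt <- qprof[[id]]$kmers
        vapply(seed_ids, function(sid) {
          S <- nrow(rprof[[sid]]$kmers[qdt, on = "kmer", nomatch = NULL])
          frac_q(S, qprof[[id]]$unique_count, eta)
        }, numeric(1L))
      } else {
        cand_set <- rprof[[id]]$kmers
        vapply(seed_ids, function(sid) {
          S <- nrow(cand_set[qprof[[sid]]$kmers, on = "kmer", nomatch = NULL])
          frac_q(S, qprof[[sid]]$unique_count, eta)
        }, numeric(1L))
      }
      # tie-break: highest frac_q, then earliest seed in seed order
      j <- order(-fr, seq_along(fr), method = "radix")[1L]
      best_seed <- seed_ids[j]
      best_frac <- fr[j]
    }
    if (is.finite(best_frac) && best_frac > threshold) {
      res_seed[i] <- best_seed
      res_frac[i] <- best_frac
    } else {
      seed_ids <- c(seed_ids, id)
      res_seed[i] <- id
    }
  }
  out <- tibble::tibble(id = corpus$id, seed_id = res_seed,
                        is_seed = corpus$id == res_seed,
                        fracq_to_seed = res_frac)
  attr(out, "threshold") <- threshold
  attr(out, "shuffle_seed") <- shuffle_seed
  attr(out, "k") <- as.integer(k)
  out
}

#' Host-balanced partitioning of a clustered corpus
#'
#' Deals cluster seeds into `n_parts` partitions for cross-validation:
#' seeds are sorted by host (alphabetically), then by cluster size
#' (descending), and distributed round-robin; cluster members then inherit
#' their seed's partition, so no cluster ever straddles a partition
#' boundary and per-host seed counts across partitions differ by at most
#' one.
#'
#' @param clusters Tibble from [hobohm_cluster()] (columns `id`,
#'   `seed_id`).
#' @param corpus Data frame with columns `id` and `host_genus` supplying
#'   the seeds' host labels.
#' @param n_parts Number of partitions (default 5).
#' @return A tibble `id`, `seed_id`, `is_seed`, `partition` (integer in
#'   `1:n_parts`).
#' @export
partition_clusters <- function(clusters, corpus, n_parts = 5L) {
  stopifnot(all(c("id", "seed_id") %in% names(clusters)), n_parts >= 2L)
  corpus <- tibble::as_tibble(corpus)
  if (!all(c("id", "host_genus") %in% names(corpus))) {
    stop("corpus must have columns id and host_genus", call. = FALSE)
  }
  host <- stats::setNames(corpus$host_genus, corpus$id)
  seeds <- unique(clusters$seed_id)
  if (anyNA(host[seeds]) || any(!nzchar(host[seeds]))) {
    stop("seed ", seeds[is.na(host[seeds]) | !nzchar(host[seeds])][1L],
         " has no host label", call. = FALSE)
  }
  size <- table(clusters$seed_id)
  st <- tibble::tibble(seed_id = seeds,
                       host = unname(host[seeds]),
                       size = as.integer(size[seeds]))
  st <- st[order(st$host, -st$size, st$seed_id, method = "radix"), ]
  st$partition <- ((seq_len(nrow(st)) - 1L) %% n_parts) + 1L
  out <- dplyr::left_join(clusters, st[, c("seed_id", "partition")],
                          by = "seed_id")
  empty <- setdiff(seq_len(n_parts), unique(out$partition))
  if (length(empty) > 0L) {
    warning("partition(s) ", paste(empty, collapse = ", "),
            " received no record (corpus smaller than n_parts)",
            call. = FALSE)
  }
  out
}

#' Split a partitioned corpus into train-test and evaluation sets
#'
#' Sets one partition aside as a final hold-out evaluation set; the
#' remaining partitions form the train-test set used for cross-validation
#' and parameter tuning. Clusters never straddle partitions, so the two id
#' sets share no near-redundant pair.
#'
#' @param partitions Tibble from [partition_clusters()].
#' @param eval_part Which partition index to hold out (default: the highest
#'   index).
#' @return A list with character vectors `train_ids` and `eval_ids`.
#' @export
split_train_eval <- function(partitions, eval_part = NULL) {
  stopifnot(all(c("id", "partition") %in% names(partitions)))
  parts <- sort(unique(partitions$partition))
  stopifnot(length(parts) >= 2L)
  eval_part <- eval_part %||% max(parts)
  if (!eval_part %in% parts) {
    stop("eval_part ", eval_part, " is not a populated partition",
         call. = FALSE)
  }
  list(train_ids = partitions$id[partitions$partition != eval_part],
       eval_ids = partitions$id[partitions$partition == eval_part])
}
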