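#' Cross-validated host-prediction accuracy
#'
#' Runs fold-wise cross-validation over a partitioned corpus: for each
#' partition in turn, a reference database is built from the remaining
#' partitions and every genome of the held-out partition is predicted
#' against it. Accuracy is computed over the queries for which a
#' prediction was made; the no-prediction rate is reported alongside.
#'
#' @param corpus Data frame with `id`, `sequence`, `host_genus` and
#'   optionally `host_species`.
#' @param partitions Tibble with columns `id` and `partition` (from
#'   [partition_clusters()], or any assignment respecting redundancy
#'   clusters).
#' @param level Evaluate at `"genus"` or `"species"` level. At species
#'   level only records with a species-rank annotation take part (both as
#'   references and as queries).
#' @param criterion,f,alpha,top_n Selection-criterion configuration, see
#'   [predict_host()].
#' @param k k-mer length.
#' @param eta,significance Similarity constants, see [score_query()].
#' @param reliable_threshold,high_confidence_threshold Tier thresholds.
#' @return An object of class `phagehost_cv`: list with `records` (tibble
#'   of per-query evaluation records: `query_id`, `fold`, `true_host`,
#'   `predicted_host`, `top_coverage`, `tier`, `correct`), `accuracy`,
#'   `n_queries`, `n_predicted`, `level`, `criterion`. Use `tidy()` /
#'   `glance()` to extract tabular views and `autoplot()` for the
#'   coverage-binned reliability profile.
#' @export
cross_validate <- function(corpus, partitions, level = c("genus", "species"),
                           criterion = 4L, f = 0.8, alpha = 6, top_n = 10L,
                           k = 16L, eta = 0.001, significance = 0.05,
                           reliable_threshold = 0.1,
                           high_confidence_threshold = 0.8) {
  level <- match.arg(level)
  corpus <- .as_corpus(corpus, "corpus")
  stopifnot(all(c("id", "partition") %in% names(partitions)))
  corpus <- dplyr::inner_join(corpus,
                              tibble::as_tibble(partitions)[, c("id", "partition")],
                              by = "id")
  if (!"host_species" %in% names(corpus)) corpus$host_species <- NA_character_
  if (level == "species") {
    corpus <- corpus[!is.na(corpus$host_species) & nzchar(corpus$host_species), ]
  }
  parts <- sort(unique(corpus$partition))
  stopifnot(length(parts) >= 2L)
  rprof <- .reference_profiles(corpus, k)
  qprof <- .query_profiles(corpus, k)
  truth <- if (level == "genus") corpus$host_genus else corpus$host_species
  names(truth) <- corpus$id

  records <- lapply(parts, function(p) {
    ref <- corpus[corpus$partition != p, ]
    db <- .db_from_profiles(ref, rprof[ref$id], k, level)
    qids <- corpus$id[corpus$partition == p]
    preds <- dplyr::bind_rows(lapply(qids, function(qid) {
      hits <- .score_one(qprof[[qid]], db, eta = eta,
                         significance = significance)
      .predict_from_hits(qid, hits, level, criterion, f, alpha, top_n,
                         reliable_threshold, high_confidence_threshold)
    }))
    tibble::tibble(
      query_id = preds$query_id, fold = p,
      true_host = unname(truth[preds$query_id]),
      predicted_host = preds$host,
      top_coverage = preds$top_coverage,
      tier = preds$tier,
      correct = ifelse(is.na(preds$host), NA,
                       preds$host == unname(truth[preds$query_id]))
    )
  })
  records <- dplyr::bind_rows(records)
  structure(
    list(records = records,
         accuracy = mean(records$correct, na.rm = TRUE),
         n_queries = nrow(records),
         n_predicted = sum(!is.na(records$correct)),
         level = level, criterion = criterion),
    class = "phagehost_cv"
  )
}

#' @export
print.phagehost_cv <- function(x, ...) {
  cat("<phagehost_cv> criterion ", x$criterion, ", ", x$level, " level: ",
      "accuracy ", sprintf("%.4f", x$accuracy), " over ", x$n_predicted,
      "/", x$n_queries, " predicted queries\n", sep = "")
  invisible(x)
}

#' Tidy cross-validation results
#'
#' `tidy()` returns the per-query evaluation records; `glance()` a one-row
#' accuracy summary.
#'
#' @param x A `phagehost_cv` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.phagehost_cv <- function(x, ...) x$records

#' @rdname tidy.phagehost_cv
#' @export
#' @exportS3Method generics::glance
glance.phagehost_cv <- function(x, ...) {
  tibble::tibble(level = x$level, criterion = x$criterion,
                 n_queries = x$n_queries, n_predicted = x$n_predicted,
                 prop_predicted = x$n_predicted / x$n_queries,
                 accuracy = x$accuracy)
}

#' Bootstrap mean and standard error of prediction accuracy
#'
#' Resamples the evaluation records with replacement `B` times and
#' recomputes accuracy (over the predicted queries of each resample).
#'
#' @param records Evaluation-record tibble with a logical `correct` column
#'   (`NA` marks no-prediction queries), e.g. `tidy(cv)`.
#' @param B Number of bootstrap resamplings (default 100; 1000 is used for
#'   pairwise criterion comparisons).
#' @param seed Integer RNG seed.
#' @return A one-row tibble: `accuracy` (point estimate), `boot_mean`,
#'   `boot_stderr`, `B`. The replicate accuracies are attached as
#'   attribute `"replicates"`.
#' @export
bootstrap_accuracy <- function(records, B = 100L, seed = 1L) {
  stopifnot(nrow(records) >= 1L, B >= 1L)
  correct <- records$correct
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      r <- correct[sample.int(length(correct), replace = TRUE)]
      mean(r, na.rm = TRUE)
    }, numeric(1L))
  })
  out <- tibble::tibble(
    accuracy = mean(correct, na.rm = TRUE),
    boot_mean = mean(reps, na.rm = TRUE),
    boot_stderr = stats::sd(reps, na.rm = TRUE),
    B = as.integer(B)
  )
  attr(out, "replicates") <- reps
  out
}

#' Accuracy by coverage bin
#'
#' Bins evaluation records by the coverage of their best hit into
#' right-closed intervals of width `bin_width`, with the last bin
#' open-ended (coverage above `1 - bin_width`), and reports per-bin
#' prediction counts and accuracy -- the reliability profile behind the
#' 0.1 / 0.8 confidence tiers.
#'
#' @inheritParams bootstrap_accuracy
#' @param bin_width Bin width (default 0.1).
#' @return A tibble: `bin` (label), `lower`, `upper`, `n`, `n_correct`,
#'   `accuracy` (`NA` for empty bins). Only predicted queries are binned.
#' @export
coverage_binned_accuracy <- function(records, bin_width = 0.1) {
  stopifnot(bin_width > 0, bin_width < 1)
  pred <- records[!is.na(records$correct), ]
  lower <- seq(0, 1 - bin_width, by = bin_width)
  breaks <- c(lower, Inf)
  labs <- c(sprintf("(%g,%g]", lower[-length(lower)], lower[-1L]),
            sprintf(">%g", lower[length(lower)]))
  bin <- cut(pred$top_coverage, breaks = breaks, labels = labs, right = TRUE)
  tab <- tibble::tibble(bin = factor(labs, levels = labs),
                        lower = lower,
                        upper = c(lower[-1L], Inf))
  cnt <- table(bin)
  cor <- tapply(pred$correct, bin, sum)
  tab$n <- as.integer(cnt[as.character(tab$bin)])
  tab$n_correct <- as.integer(ifelse(is.na(cor[as.character(tab$bin)]), 0L,
                                     cor[as.character(tab$bin)]))
  tab$accuracy <- ifelse(tab$n > 0L, tab$n_correct / tab$n, NA_real_)
  tab
}

#' Nested grid search for a selection-criterion parameter
#'
#' Tunes criterion 3's coverage fraction `f` or criterion 4's exponent
#' `alpha` by nested cross-validation: each "tripartite set" leaves one of
#' the available partitions out, and within the set an inner
#' cross-validation (each remaining partition in turn serving as test set
#' against a database of the others) scores every grid value. Because the
#' significant-hit lists do not depend on the tuned parameter, hits are
#' computed once per inner fold and re-scored across the grid.
#'
#' @inheritParams cross_validate
#' @param param `"f"` (tunes criterion 3) or `"alpha"` (criterion 4).
#' @param grid Parameter grid; defaults to `seq(0, 1, 0.05)` for `f` and
#'   `seq(0.5, 10, 0.5)` for `alpha` (which must stay positive).
#' @return An object of class `phagehost_grid`: list with `results`
#'   (tibble: `set` = excluded partition, `value`, `accuracy`,
#'   `n_predicted`, `n_queries`), `optimum` (per-set tibble: `best_value`,
#'   `best_accuracy`, `range_low`, `range_high` -- the contiguous grid
#'   range achieving at least 99% of the set's maximum accuracy) and
#'   `param`.
#' @export
tune_selection_parameter <- function(corpus, partitions,
                                     param = c("f", "alpha"), grid = NULL,
                                     level = c("genus", "species"),
                                     top_n = 10L, k = 16L, eta = 0.001,
                                     significance = 0.05) {
  param <- match.arg(param)
  level <- match.arg(level)
  grid <- grid %||% if (param == "f") seq(0, 1, by = 0.05) else
    seq(0.5, 10, by = 0.5)
  if (param == "alpha") stopifnot(all(grid > 0))
  corpus <- .as_corpus(corpus, "corpus")
  corpus <- dplyr::inner_join(corpus,
                              tibble::as_tibble(partitions)[, c("id", "partition")],
                              by = "id")
  if (!"host_species" %in% names(corpus)) corpus$host_species <- NA_character_
  if (level == "species") {
    corpus <- corpus[!is.na(corpus$host_species) & nzchar(corpus$host_species), ]
  }
  parts <- sort(unique(corpus$partition))
  stopifnot(length(parts) >= 3L)
  rprof <- .reference_profiles(corpus, k)
  qprof <- .query_profiles(corpus, k)
  truth <- if (level == "genus") corpus$host_genus else corpus$host_species
  names(truth) <- corpus$id

  # significant hits for the queries of partition `t` against a database
  # excluding partitions `e` and `t`; cached per unordered pair {e, t}
  pair_hits <- new.env(parent = emptyenv())
  hits_for <- function(e, t) {
    key <- paste(sort(c(e, t)), collapse = "_")
    if (is.null(pair_hits[[key]])) {
      ref <- corpus[!corpus$partition %in% c(e, t), ]
      db <- .db_from_profiles(ref, rprof[ref$id], k, level)
      res <- list()
      for (p in c(e, t)) {
        qids <- corpus$id[corpus$partition == p]
        res[[as.character(p)]] <- lapply(stats::setNames(qids, qids),
          function(qid) {
            h <- .score_one(qprof[[qid]], db, eta = eta,
                            significance = significance)
            h[h$significant, ]
          })
      }
      pair_hits[[key]] <- res
    }
    pair_hits[[key]][[as.character(t)]]
  }

  results <- list()
  for (e in parts) {
    inner <- setdiff(parts, e)
    fold_hits <- unlist(lapply(inner, function(t) hits_for(e, t)),
                        recursive = FALSE)
    qids <- names(fold_hits)
    has_hit <- vapply(fold_hits, function(h) nrow(h) > 0L, logical(1L))
    for (v in grid) {
      acc <- NA_real_
      if (any(has_hit)) {
        pred <- vapply(qids[has_hit], function(qid) {
          h <- fold_hits[[qid]]
          if (param == "f") criterion3(h, level, f = v)
          else select_host(h, criterion = 4L, level = level, alpha = v)$host
        }, character(1L))
        acc <- mean(pred == unname(truth[qids[has_hit]]))
      }
      results[[length(results) + 1L]] <- tibble::tibble(
        set = e, value = v, accuracy = acc,
        n_predicted = sum(has_hit), n_queries = length(qids)
      )
    }
  }
  results <- dplyr::bind_rows(results)
  optimum <- dplyr::bind_rows(lapply(split(results, results$set), function(r) {
    r <- r[order(r$value), ]
    best_i <- which.max(r$accuracy)
    ok <- r$accuracy >= 0.99 * r$accuracy[best_i]
    lo <- best_i; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- best_i; while (hi < nrow(r) && ok[hi + 1L]) hi <- hi + 1L
    tibble::tibble(set = r$set[1L], best_value = r$value[best_i],
                   best_accuracy = r$accuracy[best_i],
                   range_low = r$value[lo], range_high = r$value[hi])
  }))
  structure(list(results = results, optimum = optimum, param = param,
                 level = level),
            class = "phagehost_grid")
}

#' @export
print.phagehost_grid <- function(x, ...) {
  cat("<phagehost_grid> nested grid search over ", x$param, " (",
      x$level, " level)\n", sep = "")
  print(x$optimum)
  invisible(x)
}

#' Tidy grid-search results
#'
#' `tidy()` returns the per-set accuracy curve; `glance()` the per-set
#' optimum and its 99%-of-maximum range.
#'
#' @param x A `phagehost_grid` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.phagehost_grid <- function(x, ...) x$results

#' @rdname tidy.phagehost_grid
#' @export
#' @exportS3Method generics::glance
glance.phagehost_grid <- function(x, ...) x$optimum

#' Genome-truncation robustness experiment
#'
#' Emulates incomplete (draft/contig) query genomes: each query is replaced
#' by a contiguous sub-sequence covering a given fraction of its length and
#' re-predicted against the reference database. Reports, per fraction, the
#' share of queries receiving a prediction and the accuracy over those.
#'
#' @inheritParams cross_validate
#' @param queries Data frame with `id`, `sequence` and host-label columns
#'   matching `db$level`.
#' @param db A `host_db` (must not contain the queries themselves for an
#'   unbiased result).
#' @param fractions Genome fractions to test (default `seq(0.1, 1, 0.1)`).
#' @param placement `"prefix"` keeps the 5' end (deterministic, default);
#'   `"random"` takes a seeded random contiguous window.
#' @param seed RNG seed for `placement = "random"`.
#' @return A tibble: `fraction`, `n_queries`, `n_predicted`,
#'   `prop_predicted`, `accuracy`.
#' @export
truncation_experiment <- function(queries, db,
                                  fractions = seq(0.1, 1, by = 0.1),
                                  criterion = 4L, f = 0.8, alpha = 6,
                                  top_n = 10L, eta = 0.001,
                                  significance = 0.05,
                                  placement = c("prefix", "random"),
                                  seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(inherits(db, "host_db"), all(fractions > 0), all(fractions <= 1))
  queries <- .as_corpus(queries, "queries")
  level <- db$level
  truth_col <- if (level == "genus") "host_genus" else "host_species"
  if (!truth_col %in% names(queries)) {
    stop("queries must carry a ", truth_col, " column to evaluate a ",
         level, "-level database", call. = FALSE)
  }
  truth <- stats::setNames(queries[[truth_col]], queries$id)
  L <- nchar(queries$sequence)
  out <- lapply(sort(fractions, decreasing = TRUE), function(fr) {
    len <- pmax(0L, floor(fr * L))
    start <- if (placement == "prefix") rep(1L, nrow(queries)) else
      withr::with_seed(seed + round(fr * 1000), {
        vapply(pmax(L - len + 1L, 1L), function(m) sample.int(m, 1L),
               integer(1L))
      })
    usable <- len >= db$k
    trunc <- queries[usable, c("id", "sequence")]
    trunc$sequence <- substring(queries$sequence[usable], start[usable],
                                start[usable] + len[usable] - 1L)
    n_pred <- 0L; n_corr <- 0L
    if (nrow(trunc) > 0L) {
      preds <- predict_host(trunc, db, criterion = criterion, f = f,
                            alpha = alpha, top_n = top_n, eta = eta,
                            significance = significance)
      got <- !is.na(preds$host)
      n_pred <- sum(got)
      n_corr <- sum(preds$host[got] == unname(truth[preds$query_id[got]]))
    }
    tibble::tibble(fraction = fr, n_queries = nrow(queries),
                   n_predicted = n_pred,
                   prop_predicted = n_pred / nrow(queries),
                   accuracy = if (n_pred > 0L) n_corr / n_pred else NA_real_)
  })
  res <- dplyr::bind_rows(out)
  res[order(res$fraction), ]
}
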