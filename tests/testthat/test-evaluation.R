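# compact planted-signal corpus + partitions reused across evaluation tests
# signature sharing deliberately below the 0.7 Hobohm threshold so that
# same-host phages stay singleton clusters and spread across partitions
eval_fixture <- function(seed = 43, signature_fraction = 0.6,
                         n_hosts = 4, per_host = 4, len = 4000) {
  corpus <- simulate_phage_corpus(
    n_hosts = n_hosts, phages_per_host = per_host, genome_length = len,
    signature_fraction = signature_fraction, snp_rate = 0,
    mosaic_swap_rate = 0, seed = seed
  )
  cl <- hobohm_cluster(corpus, shuffle_seed = 1)
  pt <- suppressWarnings(partition_clusters(cl, corpus, n_parts = 4))
  list(corpus = corpus, partitions = pt)
}

test_that("perfectly host-separating corpora cross-validate to accuracy 1", {
  fx <- eval_fixture()
  cv <- cross_validate(fx$corpus, fx$partitions, level = "genus")
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$n_predicted, cv$n_queries)
  cvs <- cross_validate(fx$corpus, fx$partitions, level = "species")
  expect_equal(cvs$accuracy, 1)
  g <- glance(cv)
  expect_equal(g$prop_predicted, 1)
  expect_equal(nrow(tidy(cv)), cv$n_queries)
  # invariant to partition relabeling
  relab <- fx$partitions
  relab$partition <- 5 - relab$partition
  cv2 <- cross_validate(fx$corpus, relab, level = "genus")
  expect_equal(cv2$accuracy, cv$accuracy)
  expect_setequal(tidy(cv2)$query_id, tidy(cv)$query_id)
})

test_that("bootstrap accuracy has the expected degenerate and binomial behavior", {
  allcorrect <- tibble::tibble(correct = rep(TRUE, 20))
  b <- bootstrap_accuracy(allcorrect, B = 50, seed = 1)
  expect_equal(b$boot_mean, 1)
  expect_equal(b$boot_stderr, 0)
  half <- tibble::tibble(correct = c(TRUE, FALSE))
  b2 <- bootstrap_accuracy(half, B = 2000, seed = 2)
  expect_equal(b2$boot_mean, 0.5, tolerance = 0.05)
  expect_identical(bootstrap_accuracy(half, B = 100, seed = 7),
                   bootstrap_accuracy(half, B = 100, seed = 7))
})

test_that("bootstrap standard error shrinks like 1/sqrt(n)", {
  withr::with_seed(44, {
    ns <- c(50, 200, 800, 3200)
    se <- vapply(ns, function(n) {
      rec <- tibble::tibble(correct = sample(rep(c(TRUE, FALSE),
                                                 times = c(0.7, 0.3) * n)))
      bootstrap_accuracy(rec, B = 400, seed = n)$boot_stderr
    }, numeric(1))
    slope <- coef(lm(log(se) ~ log(ns)))[2]
    expect_equal(unname(slope), -0.5, tolerance = 0.2 * 0.5)
  })
})

test_that("coverage bins are right-closed with an open last bin and sum to n", {
  rec <- tibble::tibble(
    top_coverage = c(0.1, 0.100001, 0.95, 2.3, 0.5, NA),
    correct = c(TRUE, FALSE, TRUE, TRUE, FALSE, NA)
  )
  tab <- coverage_binned_accuracy(rec)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$n[tab$bin == "(0,0.1]"], 1L)        # 0.1 is right-closed
  expect_equal(tab$n[tab$bin == "(0.1,0.2]"], 1L)
  expect_equal(tab$n[tab$bin == ">0.9"], 2L)           # open-ended last bin
  expect_equal(sum(tab$n), 5L)                         # NA prediction excluded
  expect_true(is.na(tab$accuracy[tab$n == 0][1]))
  expect_equal(tab$accuracy[tab$bin == ">0.9"], 1)
})

test_that("nested grid search reports per-set optima and 99% ranges", {
  fx <- eval_fixture(seed = 47)
  gs <- tune_selection_parameter(fx$corpus, fx$partitions, param = "f",
                                 grid = seq(0, 1, 0.25))
  expect_equal(sort(unique(gs$results$set)), 1:4)
  expect_equal(nrow(gs$results), 4 * 5)
  # a cleanly separating corpus is flat in f at accuracy 1: range spans the grid
  expect_true(all(gs$results$accuracy == 1))
  expect_true(all(gs$optimum$range_low == 0))
  expect_true(all(gs$optimum$range_high == 1))
  ga <- tune_selection_parameter(fx$corpus, fx$partitions, param = "alpha",
                                 grid = c(1, 6))
  expect_true(all(ga$results$accuracy == 1))
  expect_error(tune_selection_parameter(fx$corpus, fx$partitions,
                                        param = "alpha", grid = c(0, 1)))
})

test_that("truncation keeps accuracy and reduces to baseline at fraction 1", {
  fx <- eval_fixture(seed = 53)
  se <- split_train_eval(fx$partitions, eval_part = 4)
  ref <- fx$corpus[fx$corpus$id %in% se$train_ids, ]
  qry <- fx$corpus[fx$corpus$id %in% se$eval_ids, ]
  db <- build_host_db(ref, k = 16)
  tr <- truncation_experiment(qry, db, fractions = c(0.25, 0.5, 1.0))
  expect_equal(tr$fraction, c(0.25, 0.5, 1.0))
  base <- predict_host(qry, db)
  got <- !is.na(base$host)
  expect_equal(tr$n_predicted[tr$fraction == 1], sum(got))
  expect_equal(tr$accuracy[tr$fraction == 1],
               mean(base$host[got] == qry$host_genus[match(base$query_id[got],
                                                           qry$id)]))
  # a fraction below k / genome length leaves no k-mers, hence no prediction
  tiny <- truncation_experiment(qry, db, fractions = 16 / 8000)
  expect_equal(tiny$n_predicted, 0L)
  expect_true(is.na(tiny$accuracy))
  # random-window placement is reproducible under the seed
  expect_identical(
    truncation_experiment(qry, db, fractions = 0.5, placement = "random",
                          seed = 3),
    truncation_experiment(qry, db, fractions = 0.5, placement = "random",
                          seed = 3)
  )
})

test_that("label-permuted corpora score near chance", {
  fx <- eval_fixture(seed = 59, n_hosts = 4, per_host = 5)
  shuf <- fx$corpus
  withr::with_seed(60, {
    perm <- sample(nrow(shuf))
    shuf$host_genus <- shuf$host_genus[perm]
    shuf$host_species <- shuf$host_species[perm]
  })
  cv <- cross_validate(shuf, fx$partitions, level = "genus")
  # 4 equi-abundant hosts: accuracy should be indistinguishable from 1/4
  bt <- binom.test(sum(cv$records$correct, na.rm = TRUE), cv$n_predicted,
                   p = 0.25)
  expect_gt(bt$p.value, 0.01)
})
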