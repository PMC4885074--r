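hits_from <- function(hosts, coverages, S = NULL) {
  n <- length(hosts)
  h <- tibble::tibble(
    ref_id = sprintf("ref%02d", seq_len(n)),
    host_genus = hosts,
    host_species = paste(hosts, "sp1"),
    S = S %||% rep(10L, n),
    coverage = coverages
  )
  h[order(-h$coverage, -h$S, h$ref_id, method = "radix"), ]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("criterion 1 picks the top-coverage host with deterministic ties", {
  expect_equal(criterion1(hits_from(c("A", "B"), c(0.9, 0.8))), "A")
  expect_equal(criterion1(hits_from("C", 0.05)), "C")
  # exact coverage tie: S descending, then ref_id ascending breaks it
  tie <- hits_from(c("A", "B"), c(0.9, 0.9), S = c(5L, 9L))
  expect_equal(criterion1(tie), "B")
  tie2 <- hits_from(c("B", "A"), c(0.9, 0.9), S = c(7L, 7L))
  expect_equal(criterion1(tie2), "B")  # ref01 precedes ref02
})

test_that("criterion 2 takes the majority of the top 10, ties to the higher coverage", {
  h <- hits_from(c(rep("B", 6), rep("A", 4), rep("A", 5)),
                 c(seq(0.9, 0.4, length.out = 10), rep(0.1, 5)))
  expect_equal(criterion2(h), "B")
  # published tie rule: 5xA best 0.9 vs 5xB best 0.95 -> B
  h2 <- hits_from(c("B", rep("A", 5), rep("B", 4)),
                  c(0.95, 0.9, 0.85, 0.8, 0.75, 0.7, 0.65, 0.6, 0.55, 0.5))
  expect_equal(criterion2(h2), "B")
  # fewer hits than top_n: majority over all of them
  h3 <- hits_from(c("A", "A", "B"), c(0.5, 0.4, 0.9))
  expect_equal(criterion2(h3, top_n = 10), "A")
})

test_that("criterion 3 thresholds at f * coverage1 inclusively", {
  h <- hits_from(c("A", "B", "B", "B"), c(1.0, 0.85, 0.85, 0.7))
  expect_equal(criterion3(h, f = 0.8), "B")  # eligible: A, B, B
  withr::with_seed(71, {
    for (i in 1:200) {
      h <- random_hits(sample(1:15, 1))
      expect_equal(criterion3(h, f = 1.0), criterion1(h))
      all_major <- phagehost:::.majority_host(h$host_genus, h$coverage)$host
      expect_equal(criterion3(h, f = 0.0), all_major)
    }
  })
})

test_that("criterion 4 sums normalized powered coverages per host", {
  h <- hits_from(c("A", "B", "B"), c(1.0, 0.9, 0.9))
  tab <- criterion4(h, alpha = 6)
  expect_equal(tab$score[tab$host == "B"], 2 * 0.9^6)  # 1.062882
  expect_equal(tab$score[tab$host == "B"], 1.062882)
  expect_equal(tab$host[1], "B")                       # 1.062882 > 1.0
  h2 <- hits_from(c("A", "B", "B", "B"), c(1.0, 0.5, 0.5, 0.5))
  tab2 <- criterion4(h2, alpha = 6)
  expect_equal(tab2$host[1], "A")                      # 1.0 > 3 * 0.5^6
  expect_equal(tab2$score[tab2$host == "B"], 3 * 0.5^6)
})

test_that("criterion 4 invariances: scale, single host, large-alpha limit", {
  withr::with_seed(72, {
    for (i in 1:200) {
      h <- random_hits(sample(1:15, 1))
      t1 <- criterion4(h, alpha = 6)
      h2 <- h
      h2$coverage <- h$coverage * 3.7
      t2 <- criterion4(h2, alpha = 6)
      expect_equal(t1$host, t2$host)
      expect_equal(t1$score, t2$score)
      # unique maximum coverage: alpha -> large approaches criterion 1
      if (sum(h$coverage == max(h$coverage)) == 1) {
        expect_equal(criterion4(h, alpha = 200)$host[1], criterion1(h))
      }
      one <- h
      one$host_genus <- "OnlyHost"
      expect_equal(criterion4(one, alpha = runif(1, 0.5, 10))$host, "OnlyHost")
    }
  })
})

test_that("all criteria agree when every hit shares one host", {
  withr::with_seed(73, {
    for (i in 1:50) {
      h <- random_hits(sample(1:10, 1), n_hosts = 1)
      hosts <- c(criterion1(h), criterion2(h), criterion3(h, f = 0.6),
                 criterion4(h, alpha = 6)$host[1])
      expect_length(unique(hosts), 1)
    }
  })
})

test_that("select_host dispatches criteria and reports a score", {
  h <- hits_from(c("A", "B", "B"), c(1.0, 0.9, 0.9))
  expect_equal(select_host(h, 1)$host, "A")
  expect_equal(select_host(h, 1)$score, 1.0)
  expect_equal(select_host(h, 4, alpha = 6)$host, "B")
  expect_equal(select_host(h, 4, alpha = 6)$score, 1.062882)
  expect_equal(select_host(h, 2)$host, "B")
  expect_equal(select_host(h, 3, f = 0.8)$host, "B")
  expect_error(select_host(h, 5), "criterion")
})

test_that("species-level selection aggregates on the full binomial", {
  h <- hits_from(c("A", "B", "B"), c(1.0, 0.9, 0.9))
  h$host_species <- c("A x", "B y", "B z")  # same genus, distinct species
  expect_equal(criterion4(h, level = "species", alpha = 6)$host[1], "A x")
  expect_equal(criterion4(h, level = "genus", alpha = 6)$host[1], "B")
})

test_that("predict_host assigns hosts and confidence tiers end to end", {
  corpus <- simulate_phage_corpus(n_hosts = 3, phages_per_host = 3,
                                  genome_length = 5000,
                                  signature_fraction = 0.8,
                                  snp_rate = 0, mosaic_swap_rate = 0,
                                  seed = 99)
  db <- build_host_db(corpus, k = 16)
  held <- corpus[c(1, 5, 9), ]
  p <- predict_host(held, db)
  expect_equal(p$host, held$host_genus)
  expect_true(all(p$tier == "highly-reliable"))  # self-match coverage ~ 1
  expect_true(all(p$top_coverage > 0.99))
  # repeated calls are identical (pure function)
  expect_identical(p, predict_host(held, db))
})

test_that("tier boundaries follow the 0.1 / 0.8 coverage thresholds", {
  at <- phagehost:::.assign_tier
  expect_equal(at(NA_real_), "no-prediction")
  expect_equal(at(0.05), "poorly-reliable")
  expect_equal(at(0.1), "poorly-reliable")   # boundary: not above 0.1
  expect_equal(at(0.100001), "reliable")
  expect_equal(at(0.8), "reliable")
  expect_equal(at(0.81), "highly-reliable")
})

test_that("queries without significant hits yield a no-prediction row", {
  refs <- tibble::tibble(id = c("r1", "r2"),
                         sequence = c(strrep("AC", 20), strrep("GA", 20)),
                         host_genus = c("Escherichia", "Bacillus"))
  db <- build_host_db(refs, k = 6)
  p <- predict_host(strrep("CT", 20), db)
  expect_equal(p$tier, "no-prediction")
  expect_true(is.na(p$host))
  expect_equal(p$n_significant, 0L)
})
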