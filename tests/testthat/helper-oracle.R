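# Independent brute-force oracle for the similarity measures: plain base R,
# no inverted index, its own complement table. Deliberately naive.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(toupper(s), "")[[1]]])), collapse = "")
}

oracle_kmers <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in seq_len(n - k + 1)) {
    w <- substr(s, i, i + k - 1)
    if (!grepl("N", w, fixed = TRUE)) out <- c(out, w)
  }
  out
}

# all five measures for one query against a small reference table
# (data.frame: id, sequence, host_genus, host_species)
oracle_score <- function(query, refs, k, eta = 0.001, significance = 0.05) {
  qk <- oracle_kmers(query, k)
  qu <- length(unique(qk))
  per_ref <- lapply(seq_len(nrow(refs)), function(i) {
    fw <- oracle_kmers(refs$sequence[i], k)
    rv <- oracle_kmers(oracle_revcomp(refs$sequence[i]), k)
    uni <- unique(c(fw, rv))
    list(lu = length(uni), l_total = length(fw) + length(rv),
         S = length(intersect(unique(qk), uni)),
         q_matched = sum(qk %in% uni))
  })
  lu_tot <- sum(vapply(per_ref, `[[`, numeric(1), "lu"))
  n_hits <- sum(vapply(per_ref, `[[`, numeric(1), "S"))
  n_ref <- nrow(refs)
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    r <- per_ref[[i]]
    if (r$S == 0) return(NULL)
    E <- n_hits * r$lu / lu_tot
    z <- (r$S - E) / sqrt(r$S + E + eta)
    p <- 2 * pnorm(-abs(z))
    data.frame(
      ref_id = refs$id[i], S = r$S, q_matched = r$q_matched, E = E, z = z,
      p = p, p_corr = min(1, p * n_ref),
      frac_q = r$S / (qu + eta), frac_d = r$S / (r$lu + eta),
      coverage = 2 * r$q_matched / (r$l_total + eta),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

random_dna <- function(n, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alpha, n, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
        collapse = "")
}

random_corpus <- function(n_rec, len_range = c(50, 300), with_n = FALSE,
                          hosts = c("Escherichia", "Salmonella", "Bacillus")) {
  g <- sample(hosts, n_rec, replace = TRUE)
  tibble::tibble(
    id = sprintf("r%02d", seq_len(n_rec)),
    sequence = vapply(seq_len(n_rec), function(i) {
      random_dna(sample(seq(len_range[1], len_range[2]), 1), with_n)
    }, character(1)),
    host_genus = g,
    host_species = paste(g, "coli")
  )
}

# randomized significant-hit list in the canonical sort order, for
# selection-criterion property tests
random_hits <- function(n, n_hosts = 3) {
  hosts <- sprintf("Host%02d", sample.int(n_hosts, n, replace = TRUE))
  h <- tibble::tibble(
    ref_id = sprintf("ref%03d", sample.int(999, n)),
    host_genus = hosts,
    host_species = paste(hosts, "sp1"),
    S = sample.int(50, n, replace = TRUE),
    coverage = round(runif(n, 0.01, 1.2), 3)
  )
  h[order(-h$coverage, -h$S, h$ref_id, method = "radix"), ]
}
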