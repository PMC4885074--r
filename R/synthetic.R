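#' Simulate a labeled phage corpus with planted host signatures
#'
#' Generates a synthetic corpus in which phages of the same host share
#' sequence: each host genus gets a pool of random "signature" segments,
#' and each phage genome is an interleaving of (possibly mutated) segments
#' from its host's pool with phage-specific random filler. Mosaicism is
#' emulated by occasionally borrowing a segment from another host's pool,
#' and divergence by per-base substitutions. The generator is deterministic
#' under `seed`.
#'
#' Defaults describe a small but realistic study corpus: 5 host genera with
#' 6 phages each, 40 kb genomes (about the median tailed-phage genome, so
#' 16-mer uniqueness behaves as in real data), 60% of each genome drawn
#' from the shared pool, 0.5% substitutions and a 2% segment-borrowing
#' rate.
#'
#' @param n_hosts Number of host genera.
#' @param phages_per_host Phages per host; either one integer or a
#'   length-`n_hosts` vector (host-abundance skew).
#' @param genome_length Genome length in bases (default 40000).
#' @param signature_fraction Fraction of each genome drawn from the host's
#'   shared segment pool, in `[0, 1]`. `0` produces a corpus with no host
#'   signal.
#' @param n_signature_segments Number of shared segments per genome
#'   (default 8).
#' @param mosaic_swap_rate Probability that a segment slot is filled from a
#'   different host's pool (default 0.02).
#' @param snp_rate Per-base substitution probability applied to each
#'   segment copy (default 0.005).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `id`, `sequence`, `host_genus`,
#'   `host_species` (one species per genus, `"<Genus> sp1"` style labels so
#'   both database flavors are exercised).
#' @examples
#' corpus <- simulate_phage_corpus(n_hosts = 2, phages_per_host = 2,
#'                                 genome_length = 1000, seed = 1)
#' corpus[, c("id", "host_genus", "host_species")]
#' @export
simulate_phage_corpus <- function(n_hosts = 5L, phages_per_host = 6L,
                                  genome_length = 40000L,
                                  signature_fraction = 0.6,
                                  n_signature_segments = 8L,
                                  mosaic_swap_rate = 0.02,
                                  snp_rate = 0.005,
                                  seed = 1L) {
  stopifnot(n_hosts >= 1L, genome_length >= 1L,
            signature_fraction >= 0, signature_fraction <= 1,
            n_signature_segments >= 1L,
            mosaic_swap_rate >= 0, mosaic_swap_rate <= 1,
            snp_rate >= 0, snp_rate <= 1)
  if (length(phages_per_host) == 1L) {
    phages_per_host <- rep(as.integer(phages_per_host), n_hosts)
  }
  stopifnot(length(phages_per_host) == n_hosts, all(phages_per_host >= 1L))
  seg_len <- floor(signature_fraction * genome_length / n_signature_segments)
  if (signature_fraction > 0 && seg_len < 1L) {
    stop("infeasible config: signature_fraction * genome_length is smaller ",
         "than one segment", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) {
    if (n <= 0L) return("")
    paste(sample(bases, n, replace = TRUE), collapse = "")
  }
  mutate_seq <- function(s, rate) {
    if (rate <= 0 || nchar(s) == 0L) return(s)
    n <- nchar(s)
    nmut <- stats::rbinom(1L, n, rate)
    if (nmut == 0L) return(s)
    pos <- sample.int(n, nmut)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1L),
                      character(1L), USE.NAMES = FALSE)
    paste(ch, collapse = "")
  }
  genera <- sprintf("Hostgenus%02d", seq_len(n_hosts))
  species <- paste0(genera, " sp1")

  withr::with_seed(seed, {
    pools <- lapply(seq_len(n_hosts), function(h) {
      if (signature_fraction == 0) return(NULL)
      replicate(n_signature_segments, rand_seq(seg_len))
    })
    rows <- list()
    for (h in seq_len(n_hosts)) {
      for (j in seq_len(phages_per_host[h])) {
        n_seg <- if (signature_fraction > 0) n_signature_segments else 0L
        segs <- character(n_seg)
        if (n_seg > 0L) {
          for (s in seq_len(n_seg)) {
            src <- h
            if (n_hosts > 1L && stats::runif(1L) < mosaic_swap_rate) {
              src <- sample(setdiff(seq_len(n_hosts), h), 1L)
            }
            segs[s] <- mutate_seq(pools[[src]][s], snp_rate)
          }
        }
        filler_total <- genome_length - n_seg * seg_len
        n_gaps <- n_seg + 1L
        gap <- filler_total %/% n_gaps
        gaps <- rep(gap, n_gaps)
        gaps[n_gaps] <- gaps[n_gaps] + filler_total - gap * n_gaps
        pieces <- character(0L)
        for (s in seq_len(n_gaps)) {
          pieces <- c(pieces, rand_seq(gaps[s]),
                      if (s <= n_seg) segs[s] else NULL)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = sprintf("phage_%s_%02d", genera[h], j),
          sequence = paste(pieces, collapse = ""),
          host_genus = genera[h],
          host_species = species[h]
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Write a corpus to FASTA and host-table fixtures
#'
#' Writes `corpus.fasta` (70-column wrapped) and `hosts.tsv` (columns
#' `id`, `host_genus`, `host_species`) into `dir`; the pair round-trips
#' through [read_phage_fasta()] and [read_host_table()].
#'
#' @param corpus Tibble from [simulate_phage_corpus()] (or any corpus with
#'   the same columns).
#' @param dir Output directory (created if missing).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_corpus_fixture <- function(corpus, dir) {
  corpus <- .as_corpus(corpus, "corpus")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "corpus.fasta")
  hosts <- file.path(dir, "hosts.tsv")
  con <- file(fasta, open = "wb")
  for (i in seq_len(nrow(corpus))) {
    writeLines(paste0(">", corpus$id[i]), con, sep = "\n")
    s <- corpus$sequence[i]
    starts <- seq.int(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con,
               sep = "\n")
  }
  close(con)
  ht <- tibble::tibble(
    id = corpus$id,
    host_genus = corpus$host_genus %||% NA_character_,
    host_species = corpus$host_species %||% NA_character_
  )
  readr::write_tsv(ht, hosts, na = "")
  invisible(c(fasta = fasta, hosts = hosts))
}
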