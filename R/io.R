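#' Read phage genomes from a multi-record FASTA file
#'
#' Parses a (possibly line-wrapped, LF or CRLF) multi-FASTA file via
#' Biostrings. The record id is the first whitespace-delimited token of
#' each header. Sequences are uppercased and must be DNA over
#' `{A,C,G,T,N}`; empty sequences and duplicate ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence` (hosts unattached;
#'   see [read_host_table()] and [attach_hosts()]).
#' @export
read_phage_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA record in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("malformed FASTA header (empty id) in ", path,
                              call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id '", ids[duplicated(ids)][1L], "' in ", path,
         call. = FALSE)
  }
  seqs <- unname(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record ", ids[nchar(seqs) == 0L][1L], " in ",
         path, call. = FALSE)
  }
  tibble::tibble(id = ids, sequence = .validate_dna(seqs, ids))
}

#' Read a host-annotation table
#'
#' Reads a tab-separated table with header columns `id`, `host_genus` and
#' optionally `host_species`. Host names of the form
#' `"<Genus> sp. <code>"` carry no species-rank information and are
#' collapsed to genus only (the species field is emptied and the genus
#' token retained).
#'
#' @param path Path to the TSV file.
#' @return A tibble `id`, `host_genus`, `host_species` (`NA` where
#'   unknown).
#' @export
read_host_table <- function(path) {
  if (!file.exists(path)) stop("host table not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("id", "host_genus") %in% names(tab))) {
    stop("host table must have columns 'id' and 'host_genus'", call. = FALSE)
  }
  if (!"host_species" %in% names(tab)) tab$host_species <- NA_character_
  tab$host_species[!is.na(tab$host_species) & !nzchar(tab$host_species)] <-
    NA_character_
  if (anyDuplicated(tab$id)) {
    stop("duplicate id '", tab$id[duplicated(tab$id)][1L], "' in host table",
         call. = FALSE)
  }
  # "<Genus> sp. CODE" carries no species information: keep genus only
  spdot <- !is.na(tab$host_species) &
    grepl("^\\S+ sp\\.(\\s|$)", tab$host_species)
  if (any(spdot)) {
    tok <- sub("^(\\S+).*$", "\\1", tab$host_species[spdot])
    miss <- is.na(tab$host_genus[spdot]) | !nzchar(tab$host_genus[spdot])
    tab$host_genus[spdot][miss] <- tok[miss]
    tab$host_species[spdot] <- NA_character_
  }
  .check_binomial(tab$host_genus, tab$host_species, tab$id)
  tibble::as_tibble(tab[, c("id", "host_genus", "host_species")])
}

#' Attach host annotations to a genome table
#'
#' Joins a host table onto a FASTA-derived genome table. Host-table ids
#' absent from the genomes produce a warning, as do genomes without a host
#' annotation (which are excluded, since they cannot enter a reference
#' database).
#'
#' @param corpus Tibble from [read_phage_fasta()].
#' @param hosts Tibble from [read_host_table()].
#' @return The annotated corpus tibble (`id`, `sequence`, `host_genus`,
#'   `host_species`).
#' @export
attach_hosts <- function(corpus, hosts) {
  corpus <- tibble::as_tibble(corpus)
  hosts <- tibble::as_tibble(hosts)
  orphan_hosts <- setdiff(hosts$id, corpus$id)
  if (length(orphan_hosts) > 0L) {
    warning(length(orphan_hosts), " host-table id(s) absent from the ",
            "genome set (e.g. ", orphan_hosts[1L], ")", call. = FALSE)
  }
  out <- dplyr::inner_join(corpus, hosts, by = "id")
  dropped <- setdiff(corpus$id, out$id)
  if (length(dropped) > 0L) {
    warning(length(dropped), " genome(s) without host annotation excluded ",
            "(e.g. ", dropped[1L], ")", call. = FALSE)
  }
  out
}

#' Write a host-prediction report
#'
#' Tab-separated report with a deterministic column order, one row per
#' query: `query_id`, `level`, `host` (empty for no-prediction queries),
#' `criterion_score`, `top_coverage`, `best_p_corr`, `n_significant`,
#' `tier`.
#'
#' @param predictions Tibble from [predict_host()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(predictions, path) {
  cols <- c("query_id", "level", "host", "criterion_score", "top_coverage",
            "best_p_corr", "n_significant", "tier")
  stopifnot(all(cols %in% names(predictions)))
  readr::write_tsv(predictions[, cols], path, na = "")
  invisible(path)
}

#' Write a per-query significant-hit report
#'
#' One row per significant hit, coverage-sorted within each query,
#' mirroring the per-reference hit list a user inspects behind a
#' prediction.
#'
#' @param hits Tibble from [score_query()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_report <- function(hits, path) {
  cols <- c("query_id", "ref_id", "host_genus", "host_species", "S", "E",
            "z", "p_corr", "frac_q", "frac_d", "coverage")
  stopifnot(all(cols %in% names(hits)))
  readr::write_tsv(hits[hits$significant, cols], path, na = "")
  invisible(path)
}
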