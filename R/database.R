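#' Build a k-mer reference database of host-annotated phages
#'
#' Decomposes every reference genome (forward strand and reverse complement)
#' into k-mers and assembles the indexed database used for scoring queries.
#' Two flavors exist: a genus-level database built from all records, and a
#' species-level database built from the subset of records whose host is
#' annotated to species rank.
#'
#' @param corpus Data frame with columns `id`, `sequence`, `host_genus` and
#'   optionally `host_species`.
#' @param k k-mer length (default 16; values 15-20 behave comparably).
#' @param level `"genus"` (all records) or `"species"` (records with a
#'   species-rank host annotation; others are dropped with a message).
#' @return An object of class `host_db`: a list with `k`, `level`,
#'   `entries` (tibble: `id`, `host_genus`, `host_species`, `lu` unique
#'   k-mer count over both strands, `l_total` total k-mer count over both
#'   strands), `index` (inverted k-mer -> reference index), `Lu_tot` (sum of
#'   `lu` over entries) and `Nref` (number of entries).
#' @seealso [score_query()], [predict_host()], [write_host_db()]
#' @export
build_host_db <- function(corpus, k = 16L, level = c("genus", "species")) {
  level <- match.arg(level)
  corpus <- .as_corpus(corpus, "corpus")
  if (nrow(corpus) == 0L) stop("empty corpus: refusing to build an empty database",
                               call. = FALSE)
  if (!"host_genus" %in% names(corpus)) {
    stop("corpus must have a host_genus column", call. = FALSE)
  }
  if (!"host_species" %in% names(corpus)) corpus$host_species <- NA_character_
  corpus$host_species[!is.na(corpus$host_species) &
                        !nzchar(corpus$host_species)] <- NA_character_
  if (anyNA(corpus$host_genus) || any(!nzchar(corpus$host_genus))) {
    bad <- corpus$id[is.na(corpus$host_genus) | !nzchar(corpus$host_genus)][1L]
    stop("record ", bad, " lacks a host_genus annotation", call. = FALSE)
  }
  .check_binomial(corpus$host_genus, corpus$host_species, corpus$id)
  if (level == "species") {
    keep <- !is.na(corpus$host_species)
    if (!all(keep)) {
      message("species-level database: dropping ", sum(!keep),
              " record(s) without a species-rank host annotation")
    }
    corpus <- corpus[keep, ]
    if (nrow(corpus) == 0L) {
      stop("no record carries a species-rank host annotation; ",
           "cannot build a species-level database", call. = FALSE)
    }
  }
  profiles <- .reference_profiles(corpus, k)
  .db_from_profiles(corpus, profiles, k, level)
}

# assemble a host_db from precomputed both-strand profiles (named by id);
# lets cross-validation rebuild fold databases without re-profiling
.db_from_profiles <- function(corpus, profiles, k, level) {
  profiles <- profiles[corpus$id]
  entries <- tibble::tibble(
    id = corpus$id,
    host_genus = corpus$host_genus,
    host_species = corpus$host_species,
    lu = unname(vapply(profiles, function(p) p$unique_count, integer(1L))),
    l_total = unname(vapply(profiles, function(p) p$total_count, integer(1L)))
  )
  entries <- entries[order(entries$id, method = "radix"), ]
  index <- data.table::rbindlist(lapply(entries$id, function(i) {
    data.table::data.table(kmer = profiles[[i]]$kmers$kmer, ref_id = i)
  }))
  data.table::setkey(index, kmer)
  structure(
    list(k = as.integer(k), level = level, entries = entries, index = index,
         Lu_tot = sum(entries$lu), Nref = nrow(entries)),
    class = "host_db"
  )
}

#' @export
print.host_db <- function(x, ...) {
  cat("<host_db> ", x$level, "-level, k=", x$k, ": ", x$Nref,
      " reference phages, ", x$Lu_tot, " unique k-mers (",
      length(unique(x$entries$host_genus)), " host genera)\n", sep = "")
  invisible(x)
}

#' @rdname glance.host_db
#' @export
#' @exportS3Method generics::glance
glance.host_db <- function(x, ...) {
  tibble::tibble(k = x$k, level = x$level, n_ref = x$Nref,
                 lu_tot = x$Lu_tot,
                 n_host_genera = length(unique(x$entries$host_genus)),
                 n_host_species = sum(!is.na(unique(x$entries$host_species))))
}

#' Summarise a reference database
#'
#' `glance()` returns a one-row tibble of database-level totals; `tidy()`
#' returns the per-reference entry table.
#'
#' @param x A `host_db`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.host_db <- function(x, ...) x$entries

.DB_FORMAT <- "phagehost_db"
.DB_VERSION <- 1L

#' Serialize a reference database to a plain-text file
#'
#' The on-disk format is a versioned, tab-separated text file with a
#' canonical (sorted) record order, so saving the same database twice
#' produces byte-identical files and `read_host_db(write_host_db(db))`
#' round-trips exactly.
#'
#' @param db A `host_db`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_host_db <- function(db, path) {
  stopifnot(inherits(db, "host_db"))
  kv <- db$index[order(ref_id, kmer)]
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(..., sep = "\t"), con, sep = "\n")
  wl(.DB_FORMAT, .DB_VERSION)
  wl("k", db$k)
  wl("level", db$level)
  wl("nref", db$Nref)
  wl("lu_tot", db$Lu_tot)
  wl("entries", nrow(db$entries))
  e <- db$entries
  wl(e$id, e$host_genus, ifelse(is.na(e$host_species), "", e$host_species),
     e$lu, e$l_total)
  wl("kmers", nrow(kv))
  wl(kv$ref_id, kv$kmer)
  invisible(path)
}

#' Load a reference database written by [write_host_db()]
#'
#' @param path File produced by [write_host_db()].
#' @return A `host_db`.
#' @export
read_host_db <- function(path) {
  lines <- readLines(path)
  fail <- function(why) stop("corrupt or truncated database file '", path,
                             "': ", why, call. = FALSE)
  if (length(lines) < 7L) fail("too short")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr[1L], .DB_FORMAT)) fail("not a phagehost database")
  if (!identical(as.integer(hdr[2L]), .DB_VERSION)) {
    stop("database file version ", hdr[2L], " not supported (expected ",
         .DB_VERSION, ")", call. = FALSE)
  }
  field <- function(i, key) {
    p <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (!identical(p[1L], key)) fail(paste0("expected '", key, "' header"))
    p[2L]
  }
  k <- as.integer(field(2L, "k"))
  level <- field(3L, "level")
  nref <- as.integer(field(4L, "nref"))
  lu_tot <- as.integer(field(5L, "lu_tot"))
  n_ent <- as.integer(field(6L, "entries"))
  if (length(lines) < 7L + n_ent) fail("entry section incomplete")
  ent <- utils::read.table(
    text = lines[seq.int(7L, 6L + n_ent)], sep = "\t", quote = "",
    col.names = c("id", "host_genus", "host_species", "lu", "l_total"),
    colClasses = c("character", "character", "character", "integer", "integer"),
    na.strings = NULL
  )
  ent$host_species[!nzchar(ent$host_species)] <- NA_character_
  n_km <- as.integer(field(7L + n_ent, "kmers"))
  km_lines <- lines[-seq_len(7L + n_ent)]
  if (length(km_lines) != n_km) fail("k-mer section incomplete")
  parts <- data.table::tstrsplit(km_lines, "\t", fixed = TRUE)
  index <- data.table::data.table(kmer = parts[[2L]], ref_id = parts[[1L]])
  data.table::setkey(index, kmer)
  entries <- tibble::as_tibble(ent)
  db <- structure(
    list(k = k, level = level, entries = entries, index = index,
         Lu_tot = lu_tot, Nref = nref),
    class = "host_db"
  )
  if (db$Nref != nrow(entries) || db$Lu_tot != sum(entries$lu)) {
    fail("totals do not match entries")
  }
  db
}
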