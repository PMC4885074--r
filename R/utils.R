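# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# validate a character vector of DNA sequences over {A,C,G,T,N}
# (case-insensitive); returns the uppercased sequences
.validate_dna <- function(sequences, ids = NULL) {
  if (!is.character(sequences)) {
    stop("sequences must be a character vector", call. = FALSE)
  }
  up <- toupper(sequences)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) {
    who <- if (!is.null(ids)) ids[bad][1L] else which(bad)[1L]
    ch <- regmatches(up[bad][1L], regexpr("[^ACGTN]", up[bad][1L]))
    stop("sequence ", who, " contains non-IUPAC DNA character '", ch,
         "' (allowed: A, C, G, T, N)", call. = FALSE)
  }
  up
}

# coerce the common query/corpus inputs to a two-column tibble (id, sequence);
# extra columns (host labels) are carried through untouched
.as_corpus <- function(x, arg = "x") {
  if (is.character(x)) {
    ids <- names(x) %||% if (length(x) == 1L) "query" else
      paste0("query_", seq_along(x))
    x <- tibble::tibble(id = ids, sequence = unname(x))
  }
  if (!is.data.frame(x)) {
    stop(arg, " must be a data frame with columns id and sequence, ",
         "or a character vector of sequences", call. = FALSE)
  }
  if (!all(c("id", "sequence") %in% names(x))) {
    stop(arg, " must have columns 'id' and 'sequence'", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (anyNA(x$id) || any(!nzchar(x$id))) {
    stop(arg, ": record ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(x$id)) {
    stop(arg, ": duplicate record id '", x$id[duplicated(x$id)][1L], "'",
         call. = FALSE)
  }
  x$sequence <- .validate_dna(x$sequence, x$id)
  x
}

.check_binomial <- function(host_genus, host_species, ids) {
  has <- !is.na(host_species) & nzchar(host_species)
  ok <- !has | startsWith(host_species, paste0(host_genus, " "))
  if (!all(ok)) {
    stop("record ", ids[!ok][1L], ": host_species '",
         host_species[!ok][1L], "' does not begin with host_genus '",
         host_genus[!ok][1L], "' followed by a space", call. = FALSE)
  }
  invisible(TRUE)
}
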