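#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or A3M file into an `msa` object: a character
#' matrix with one row per sequence and one column per query position, query
#' first.  In A3M files, lowercase characters mark insertions relative to
#' the query; those states are removed so every row has the query's column
#' count.  Non-standard residue codes (B, Z, X, U, O, J, ...) and the dot
#' used by some A3M writers are canonicalized to the gap state, preserving
#' alignment depth and column register.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` for aligned FASTA, `"a3m"` for the
#'   lowercase-insertion A3M dialect.
#' @return an object of class `msa`: character matrix (`m` rows, `N`
#'   columns) over the 21-state alphabet (20 amino acids + `"-"`), with
#'   attributes `query_id` and `ids`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">q", "ACDE", ">h1", "AC-E"), f)
#' aln <- read_msa(f)
#' dim(aln)
#' @export
read_msa <- function(path, format = c("fasta", "a3m")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_varfit("alignment file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop_varfit("empty alignment file: ", path)
  ids <- names(seqs)
  rows <- as.character(seqs)
  if (format == "a3m") {
    # lowercase = insertion relative to the query; drop those states
    rows <- vapply(rows, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      paste(ch[!(ch %in% letters)], collapse = "")
    }, character(1), USE.NAMES = FALSE)
    rows <- gsub(".", "-", rows, fixed = TRUE)
  }
  rows <- toupper(rows)
  n <- unique(nchar(rows))
  if (length(n) != 1L)
    stop_varfit("ragged alignment after canonicalization in ", path,
                " (row lengths ", paste(sort(n), collapse = ", "), ")")
  if (n == 0L) stop_varfit("alignment has zero columns: ", path)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  mat[!(mat %in% AA21)] <- GAP
  new_msa(mat, query_id = ids[1L], ids = ids)
}

new_msa <- function(mat, query_id = "query", ids = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L, ncol(mat) >= 1L)
  if (is.null(ids)) ids <- c(query_id, paste0("seq", seq_len(nrow(mat) - 1L)))
  structure(mat, class = "msa", query_id = query_id, ids = ids)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns\n",
              nrow(x), ncol(x)))
  cat("Query: ", attr(x, "query_id"), "\n", sep = "")
  cat("       ", paste(x[1L, seq_len(min(60L, ncol(x)))], collapse = ""),
      if (ncol(x) > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Query sequence of an alignment
#'
#' @param msa an [`msa`][read_msa] object.
#' @param ungapped drop gap columns of the query row?
#' @return character vector of residues (row 1 of the alignment).
#' @export
msa_query <- function(msa, ungapped = FALSE) {
  q <- msa[1L, ]
  if (ungapped) q <- q[q != GAP]
  q
}

#' Write an alignment to aligned FASTA or A3M
#'
#' @param msa an [`msa`][read_msa] object.
#' @param path output path.
#' @param format output dialect; `"a3m"` writes the same columns (no
#'   insertions are reconstructed).
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, format = c("fasta", "a3m")) {
  format <- match.arg(format)
  ids <- attr(msa, "ids") %||% paste0("seq", seq_len(nrow(msa)))
  lines <- character(2L * nrow(msa))
  lines[c(TRUE, FALSE)] <- paste0(">", ids)
  lines[c(FALSE, TRUE)] <- apply(msa, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a single-site variant
#'
#' A variant is a 1-based position in the query sequence, the wild-type
#' residue (validated against the query when one is supplied) and the
#' mutant residue.
#'
#' @param position 1-based position in the query sequence.
#' @param wt,mt one-letter wild-type and mutant amino acids.
#' @param query optional query sequence (character vector) to validate
#'   `wt` against; a mismatch is an error, never a warning, because silent
#'   coordinate drift is the classic variant-annotation bug.
#' @return a `variant` object (named list).
#' @examples
#' variant(2, "C", "W", query = c("A", "C", "D"))
#' @export
variant <- function(position, wt, mt, query = NULL) {
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position) || position < 1L)
    stop_varfit("variant position must be a positive integer")
  if (!(wt %in% AA20)) stop_varfit("wild-type residue '", wt,
                                   "' is not a standard amino acid")
  if (!(mt %in% AA20)) stop_varfit("mutant residue '", mt,
                                   "' is not a standard amino acid")
  if (!is.null(query)) {
    if (position > length(query))
      stop_varfit("variant position ", position,
                  " beyond query length ", length(query))
    if (query[position] != wt)
      stop_varfit("wild-type mismatch at position ", position,
                  ": variant says '", wt, "', query has '",
                  query[position], "'")
  }
  structure(list(position = position, wt = wt, mt = mt), class = "variant")
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("%s%d%s\n", x$wt, x$position, x$mt))
  invisible(x)
}

#' @export
format.variant <- function(x, ...) sprintf("%s%d%s", x$wt, x$position, x$mt)

#' Parse variant keys in common notations
#'
#' Accepts `"A123V"` one-letter keys and `"p.Ala123Val"` / `"Ala123Val"`
#' three-letter HGVS-style keys, normalizing both to (position, wt, mt).
#'
#' @param key character vector of variant keys.
#' @return data.frame with columns `position`, `wt`, `mt`.
#' @examples
#' parse_variant_key(c("A2V", "p.Ala2Val"))
#' @export
parse_variant_key <- function(key) {
  key <- trimws(key)
  out <- data.frame(position = integer(length(key)),
                    wt = character(length(key)),
                    mt = character(length(key)))
  re1 <- "^([ACDEFGHIKLMNPQRSTVWY])([0-9]+)([ACDEFGHIKLMNPQRSTVWY])$"
  re3 <- "^(?:p\\.)?([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$"
  for (i in seq_along(key)) {
    k <- key[i]
    if (grepl(re1, k)) {
      out$wt[i] <- sub(re1, "\\1", k)
      out$position[i] <- as.integer(sub(re1, "\\2", k))
      out$mt[i] <- sub(re1, "\\3", k)
    } else if (grepl(re3, k)) {
      w3 <- toupper(sub(re3, "\\1", k))
      m3 <- toupper(sub(re3, "\\3", k))
      if (!(w3 %in% names(AA3TO1)) || !(m3 %in% names(AA3TO1)))
        stop_varfit("unknown residue code in variant key '", k, "'")
      out$wt[i] <- AA3TO1[[w3]]
      out$position[i] <- as.integer(sub(re3, "\\2", k))
      out$mt[i] <- AA3TO1[[m3]]
    } else {
      stop_varfit("cannot parse variant key '", k, "'")
    }
  }
  out
}
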