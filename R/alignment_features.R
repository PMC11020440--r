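#' Regularized amino-acid frequencies of an alignment
#'
#' Computes pseudocount-regularized per-column and alignment-wide
#' frequencies over 21 states (20 amino acids and the gap):
#' \deqn{f_i(a) = \frac{c_i(a)}{m}(1-\theta) + \frac{\theta}{21}, \qquad
#'       f(a)   = \frac{c(a)}{mN}(1-\theta) + \frac{\theta}{21},}
#' where \eqn{c_i(a)} and \eqn{c(a)} count occurrences of state \eqn{a} in
#' column \eqn{i} and in the whole alignment, \eqn{m} is the alignment
#' depth and \eqn{N} its length.  The gap is counted as the 21st state.
#'
#' @param msa an [`msa`][read_msa] object.
#' @param theta pseudocount strength in `[0, 1]`; default `0.01`.
#' @return an object of class `freq_model` with elements `f_col` (N x 21
#'   matrix), `f_global` (length-21 vector), raw counts `c_col`,
#'   `c_global`, and `theta`, `m`, `N`.
#' @examples
#' aln <- new_msa_from_strings(c("ACDE", "AC-E", "AADE"))
#' fm <- regularized_frequencies(aln)
#' rowSums(fm$f_col)   # each column sums to 1
#' @export
regularized_frequencies <- function(msa, theta = 0.01) {
  if (!inherits(msa, "msa")) stop_varfit("msa must be an 'msa' object")
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    stop_varfit("theta must be a single number in [0, 1]")
  m <- nrow(msa); N <- ncol(msa)
  if (m < 1L || N < 1L) stop_varfit("empty alignment")
  c_col <- t(apply(msa, 2L, function(col)
    tabulate(factor(col, levels = AA21), nbins = 21L)))
  dimnames(c_col) <- list(NULL, AA21)
  c_global <- colSums(c_col)
  f_col <- (c_col / m) * (1 - theta) + theta / 21
  f_global <- (c_global / (m * N)) * (1 - theta) + theta / 21
  structure(list(f_col = f_col, f_global = f_global,
                 c_col = c_col, c_global = c_global,
                 theta = theta, m = m, N = N),
            class = "freq_model")
}

#' @export
print.freq_model <- function(x, ...) {
  cat(sprintf("Regularized frequency model: %d columns, depth %d, theta = %g\n",
              x$N, x$m, x$theta))
  invisible(x)
}

#' Build an msa object from aligned strings
#'
#' Convenience constructor used throughout examples and tests; row 1 is the
#' query.  Characters outside the 21-state alphabet are canonicalized to
#' the gap.
#'
#' @param rows character vector of aligned sequences, equal lengths.
#' @param query_id,ids optional sequence identifiers.
#' @return an [`msa`][read_msa] object.
#' @export
new_msa_from_strings <- function(rows, query_id = "query", ids = NULL) {
  rows <- toupper(rows)
  if (length(unique(nchar(rows))) != 1L) stop_varfit("ragged alignment")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  mat[!(mat %in% AA21)] <- GAP
  new_msa(mat, query_id = query_id, ids = ids)
}

#' Conservation index of an alignment column
#'
#' Euclidean distance between the regularized frequency vector of column
#' `i` and the alignment-wide vector, summed over the 20 standard amino
#' acids only — the gap state contributes to the frequencies but is
#' excluded from the distance:
#' \deqn{\mathrm{CI}(i) = \Big[\sum_{a \in A}(f_i(a)-f(a))^2\Big]^{1/2}.}
#'
#' @param freq a [`freq_model`][regularized_frequencies].
#' @param i column index (1-based); vectorized.  Default: all columns.
#' @return numeric vector of CI scores, one per requested column.
#' @export
conservation_index <- function(freq, i = seq_len(freq$N)) {
  if (!inherits(freq, "freq_model")) stop_varfit("freq must be a freq_model")
  if (any(i < 1L | i > freq$N)) stop_varfit("column index out of bounds")
  d <- freq$f_col[i, AA20, drop = FALSE] -
    rep(freq$f_global[AA20], each = length(i))
  sqrt(rowSums(d^2))
}

#' Log-odds ratio of mutant versus wild-type column frequencies
#'
#' \deqn{\mathrm{LOR}(i) = \mathrm{logit} f_i(mt) - \mathrm{logit} f_i(wt)}
#' with the natural-log logit.  Requires the regularized frequencies to be
#' strictly inside (0, 1), which any `theta > 0` guarantees.
#'
#' @param freq a [`freq_model`][regularized_frequencies].
#' @param variant a [variant()].
#' @return the LOR score (scalar).
#' @export
log_odds_ratio <- function(freq, variant) {
  if (!inherits(freq, "freq_model")) stop_varfit("freq must be a freq_model")
  i <- variant$position
  if (i < 1L || i > freq$N) stop_varfit("variant position out of bounds")
  fw <- freq$f_col[i, variant$wt]
  fm <- freq$f_col[i, variant$mt]
  if (fw <= 0 || fw >= 1 || fm <= 0 || fm >= 1)
    stop_varfit("degenerate logit: frequency at the boundary of (0,1); ",
                "use theta > 0")
  unname(log(fm / (1 - fm)) - log(fw / (1 - fw)))
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-separated matrix text format (comment
#' lines starting with `#`, a header row of residues, one labelled row per
#' residue).  Only the 20 standard amino acids are retained.
#'
#' @param path path to the matrix file; default: the bundled BLOSUM62.
#' @return a 20 x 20 symmetric integer matrix with dimnames in `AA20`
#'   order, class `substitution_matrix`, attribute `name`.
#' @export
read_substitution_matrix <- function(path = NULL) {
  name <- "BLOSUM62"
  if (is.null(path)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "varfit")
  } else {
    name <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labs <- vapply(rows, `[`, character(1), 1L)
  vals <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1L])))
  dimnames(vals) <- list(labs, header)
  keep_r <- rownames(vals) %in% AA20
  keep_c <- colnames(vals) %in% AA20
  m <- vals[keep_r, keep_c, drop = FALSE][AA20, AA20]
  if (!isTRUE(all.equal(m, t(m))))
    stop_varfit("substitution matrix is not symmetric: ", path)
  structure(m, class = c("substitution_matrix", class(m)), name = name)
}

#' PROVEAN-style delta-alignment score
#'
#' For each homolog row whose state at the variant column is not a gap,
#' the score change of substituting the wild-type by the mutant against
#' that homolog's residue is `s(mt, h_i) - s(wt, h_i)`; the score is the
#' unweighted mean of these deltas over the covering homologs.  Pairwise
#' alignments are reused from the MSA rather than recomputed per variant.
#' If no homolog covers the column the score is 0 and the `no_coverage`
#' attribute is set.
#'
#' @param msa an [`msa`][read_msa]; row 1 is the wild-type.
#' @param variant a [variant()] (validated against the query row).
#' @param matrix a [`substitution_matrix`][read_substitution_matrix];
#'   default BLOSUM62.
#' @return scalar score with logical attribute `no_coverage`.
#' @export
provean_score <- function(msa, variant, matrix = read_substitution_matrix()) {
  if (!inherits(msa, "msa")) stop_varfit("msa must be an 'msa' object")
  q <- msa_query(msa)
  v <- variant(variant$position, variant$wt, variant$mt, query = q)
  if (nrow(msa) < 2L)
    return(structure(0, no_coverage = TRUE))
  states <- msa[-1L, v$position]
  states <- states[states != GAP]
  if (length(states) == 0L)
    return(structure(0, no_coverage = TRUE))
  deltas <- matrix[v$mt, states] - matrix[v$wt, states]
  structure(mean(deltas), no_coverage = FALSE)
}
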