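#' Load a per-variant external feature table
#'
#' Reads a CSV carrying scores of external structure-based predictors
#' (columns among `PoP`, `MAE`, `SNP`, renameable through `schema`).
#' Variants are keyed either by a `variant` column (`"A123V"` or
#' `"p.Ala123Val"`) or by `position`/`wt`/`mt` columns; keys are
#' normalized to (position, wt, mt).  Missing cells stay `NA` — absent,
#' never zero.
#'
#' @param path CSV path.
#' @param schema optional named character vector mapping file column names
#'   to canonical ones, e.g. `c(popmusic = "PoP")`.
#' @return data.frame of class `feature_table` with columns `position`,
#'   `wt`, `mt` and any of `PoP`, `MAE`, `SNP`.
#' @export
load_feature_table <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema))
    names(df)[match(names(schema), names(df))] <- unname(schema)
  if ("variant" %in% names(df)) {
    key <- parse_variant_key(df$variant)
    df$position <- key$position; df$wt <- key$wt; df$mt <- key$mt
    df$variant <- NULL
  }
  need <- c("position", "wt", "mt")
  if (!all(need %in% names(df)))
    stop_varfit("feature table needs a 'variant' column or ",
                "'position', 'wt', 'mt' columns: ", path)
  vkey <- paste0(df$wt, df$position, df$mt)
  if (anyDuplicated(vkey))
    stop_varfit("duplicate variant keys in ", path, ": ",
                paste(unique(vkey[duplicated(vkey)]), collapse = ", "))
  feat <- intersect(STR_FEATURES, names(df))
  for (f in feat) {
    bad <- !is.na(df[[f]]) & !is.finite(suppressWarnings(as.numeric(df[[f]])))
    raw_na <- is.na(df[[f]])
    num <- suppressWarnings(as.numeric(df[[f]]))
    if (any(is.na(num) & !raw_na))
      stop_varfit("non-numeric value in column '", f, "' of ", path,
                  " (variant ", vkey[which(is.na(num) & !raw_na)[1L]], ")")
    if (any(bad)) stop_varfit("non-finite value in column '", f, "'")
    df[[f]] <- num
  }
  out <- df[, c(need, feat), drop = FALSE]
  base::structure(out, class = c("feature_table", "data.frame"))
}

#' Write a feature table to CSV
#'
#' @param table a `feature_table` (or compatible data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assemble the eight-feature vectors for a set of variants
#'
#' Joins the evolutionary features (PVS, CI, LOR, PYF computed from the
#' alignment and the Potts model), the structural RSA (through the
#' structure-to-sequence position map) and the external predictor columns
#' (PoP, MAE, SNP) into one row per variant.  Nothing is imputed here:
#' unavailable members are `NA` and flagged in the `missing_*` columns.
#'
#' @param variants data.frame with `position`, `wt`, `mt`.
#' @param msa an [`msa`][read_msa]; its query must equal `query`.
#' @param potts optional `potts_model` fitted on `msa` (for PYF).
#' @param rsa_by_position optional numeric vector: RSA per query position
#'   (NA for unresolved positions).
#' @param external optional [`feature_table`][load_feature_table].
#' @param matrix substitution matrix for PVS.
#' @param theta pseudocount for the frequency model.
#' @return data.frame with `position`, `wt`, `mt`, the eight feature
#'   columns, and logical availability flags.
#' @export
assemble_features <- function(variants, msa, potts = NULL,
                              rsa_by_position = NULL, external = NULL,
                              matrix = read_substitution_matrix(),
                              theta = 0.01) {
  q <- msa_query(msa)
  fm <- regularized_frequencies(msa, theta = theta)
  n <- nrow(variants)
  out <- data.frame(position = variants$position, wt = variants$wt,
                    mt = variants$mt,
                    RSA = NA_real_, PoP = NA_real_, MAE = NA_real_,
                    SNP = NA_real_, PVS = NA_real_, CI = NA_real_,
                    LOR = NA_real_, PYF = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    v <- variant(variants$position[k], variants$wt[k], variants$mt[k],
                 query = q)
    out$CI[k] <- conservation_index(fm, v$position)
    out$LOR[k] <- log_odds_ratio(fm, v)
    out$PVS[k] <- as.numeric(provean_score(msa, v, matrix = matrix))
    if (!is.null(potts))
      out$PYF[k] <- as.numeric(variant_delta_fitness(potts, q, v))
  }
  if (!is.null(rsa_by_position))
    out$RSA <- rsa_by_position[out$position]
  if (!is.null(external)) {
    km <- match(paste0(out$wt, out$position, out$mt),
                paste0(external$wt, external$position, external$mt))
    for (f in intersect(STR_FEATURES, names(external)))
      out[[f]] <- external[[f]][km]
  }
  for (f in FEATURE_NAMES)
    out[[paste0("missing_", f)]] <- is.na(out[[f]])
  out
}

#' Median-impute missing feature values
#'
#' Replaces each absent feature value by the per-feature median over the
#' table (the convention used when an external predictor does not cover
#' every variant).  Imputation flags (`missing_*` columns) are kept.
#'
#' @param features data.frame with (a subset of) the eight feature
#'   columns.
#' @param columns which columns to impute; default: the eight features
#'   present in the table.
#' @return the completed table.
#' @export
impute_missing <- function(features, columns = intersect(FEATURE_NAMES,
                                                         names(features))) {
  for (f in columns) {
    x <- features[[f]]
    miss <- is.na(x)
    if (all(miss))
      stop_varfit("feature '", f, "' is absent for every variant; ",
                  "cannot impute")
    if (any(miss)) {
      features[[f]][miss] <- stats::median(x[!miss])
      flag <- paste0("missing_", f)
      if (!(flag %in% names(features))) features[[flag]] <- miss
    }
  }
  features
}
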