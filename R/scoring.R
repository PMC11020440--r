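#' Raw linear fitness score of feature vectors
#'
#' Applies the nine fitted coefficients to complete feature rows.  The
#' output is deliberately unclamped: 1 means wild-type-like fitness, 0 or
#' below non-functional, above 1 fitter than wild type.
#'
#' @param features data.frame (or named vector) with the eight feature
#'   columns, no missing values.
#' @param alpha named coefficient vector from [coef.varfit()] or a
#'   [varfit_coefficients()] object (its `alpha` part is used).
#' @return numeric vector of raw scores.
#' @export
linear_score <- function(features, alpha) {
  if (inherits(alpha, "varfit_coefficients")) alpha <- alpha$alpha
  if (is.null(dim(features)))
    features <- as.data.frame(as.list(features))
  missing_cols <- setdiff(FEATURE_NAMES, names(features))
  if (length(missing_cols) > 0L)
    stop_varfit("feature column(s) missing: ",
                paste(missing_cols, collapse = ", "))
  X <- as.matrix(features[, FEATURE_NAMES, drop = FALSE])
  if (anyNA(X))
    stop_varfit("features contain missing values; run impute_missing() first")
  unname(drop(X %*% alpha[FEATURE_NAMES])) + alpha[["(Intercept)"]]
}

relu <- function(x) pmax(x, 0)

#' Rescaled stability-predictor score (affine)
#'
#' `beta[1] * SNP + beta[2]`: an affine rescaling of an external
#' deleteriousness score onto the fitness scale.
#'
#' @param snp numeric score(s).
#' @param beta length-2 coefficient vector (slope, intercept).
#' @return numeric vector.
#' @export
rescaled_snp <- function(snp, beta) {
  if (length(beta) != 2L || any(!is.finite(beta)))
    stop_varfit("beta must be two finite numbers")
  beta[1L] * snp + beta[2L]
}

#' Rescaled stability-predictor score, clamped to [0, 1]
#'
#' The double-ReLU form
#' `-ReLU(-ReLU(gamma[1]*pop + gamma[2]) + 1) + 1`, which is algebraically
#' the affine map clamped to the unit interval.  Implemented literally in
#' the ReLU form; the clamp closed form is verified against it in the test
#' suite.
#'
#' @param pop numeric score(s).
#' @param gamma length-2 coefficient vector (slope, intercept).
#' @return numeric vector in `[0, 1]`.
#' @export
rescaled_pop <- function(pop, gamma) {
  if (length(gamma) != 2L || any(!is.finite(gamma)))
    stop_varfit("gamma must be two finite numbers")
  -relu(-relu(gamma[1L] * pop + gamma[2L]) + 1) + 1
}

#' Structural and evolutionary contributions of a score
#'
#' Splits the linear score into its structural block
#' `STR = a2*PoP + a3*MAE + a4*SNP` and evolutionary block
#' `EVO = a5*PVS + a6*CI + a7*LOR + a8*PYF`.  RSA and the intercept
#' belong to neither block, so `STR + EVO + a1*RSA + a9` equals the full
#' score exactly.
#'
#' @inheritParams linear_score
#' @return data.frame with columns `STR` and `EVO`.
#' @export
decompose_score <- function(features, alpha) {
  if (inherits(alpha, "varfit_coefficients")) alpha <- alpha$alpha
  if (is.null(dim(features)))
    features <- as.data.frame(as.list(features))
  X <- as.matrix(features[, FEATURE_NAMES, drop = FALSE])
  if (anyNA(X)) stop_varfit("features contain missing values")
  data.frame(
    STR = drop(X[, STR_FEATURES, drop = FALSE] %*% alpha[STR_FEATURES]),
    EVO = drop(X[, EVO_FEATURES, drop = FALSE] %*% alpha[EVO_FEATURES]))
}

population_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Interpretability z-scores over a protein's mutational landscape
#'
#' Standardizes the raw score and its structural/evolutionary blocks over
#' all scored mutations of the protein:
#' \deqn{Z = (x - \mu[x]) / \sigma[x]}
#' with the population (divide-by-n) standard deviation, since the
#' landscape is a fixed finite set, not a sample.  Negative `Z_evo` marks
#' substitutions to residues rarely seen at the position across evolution;
#' negative `Z_str` marks substitutions that destabilize the fold more
#' than the average mutation.
#'
#' The reference set defaults to the complete single-site landscape (19
#' substitutions at every position); standardizing over a subset is
#' allowed but warned about, because the resulting z-scores are relative
#' to that subset only.
#'
#' @param table data.frame with columns `score`, `STR`, `EVO` (and
#'   optionally `position` for the completeness check).
#' @return `table` with columns `Z`, `Z_str`, `Z_evo` appended.
#' @export
zscores <- function(table) {
  need <- c("score", "STR", "EVO")
  if (!all(need %in% names(table)))
    stop_varfit("table needs columns ", paste(need, collapse = ", "))
  if ("position" %in% names(table)) {
    n_expected <- 19L * length(unique(table$position))
    if (nrow(table) < n_expected)
      warning("z-scores standardized over a subset of the landscape (",
              nrow(table), " of ", n_expected, " mutations)", call. = FALSE)
  }
  z <- function(x, what) {
    s <- population_sd(x)
    if (s == 0) stop_varfit("cannot z-score ", what, ": scores are constant")
    (x - mean(x)) / s
  }
  table$Z <- z(table$score, "score")
  table$Z_str <- z(table$STR, "STR")
  table$Z_evo <- z(table$EVO, "EVO")
  table
}

#' Per-residue average z-scores
#'
#' Averages each z-score over the substitutions of every residue — the
#' per-residue values used to colour a structure by average mutational
#' effect.
#'
#' @param table a z-scored table from [zscores()] with a `position`
#'   column.
#' @return data.frame with one row per position: mean `Z`, `Z_str`,
#'   `Z_evo` and the substitution count.
#' @export
per_residue_summary <- function(table) {
  if (nrow(table) == 0L) stop_varfit("empty score table")
  pos <- sort(unique(table$position))
  agg <- function(col) as.numeric(
    tapply(table[[col]], factor(table$position, levels = pos), mean))
  data.frame(position = pos, n = as.integer(table(factor(table$position,
                                                         levels = pos))),
             Z = agg("Z"), Z_str = agg("Z_str"), Z_evo = agg("Z_evo"))
}

#' Mean z-score over a subset of mutations
#'
#' Utility for gain-of-function-style analyses: the average z-score of a
#' chosen subset of the landscape (e.g. variants whose experimental
#' fitness exceeds a cutoff).
#'
#' @param z numeric z-score vector.
#' @param subset logical or integer index of the subset.
#' @return the subset mean.
#' @export
subset_mean_zscore <- function(z, subset) {
  zs <- z[subset]
  if (length(zs) == 0L) stop_varfit("empty subset")
  mean(zs)
}

#' Bundle fitted model coefficients with provenance
#'
#' @param alpha nine named linear coefficients (see [varfit()]).
#' @param beta,gamma optional length-2 vectors of the affine and clamped
#'   rescaling models.
#' @param provenance free-text description of the training data.
#' @return object of class `varfit_coefficients`.
#' @export
varfit_coefficients <- function(alpha, beta = NULL, gamma = NULL,
                                provenance = "unspecified") {
  expected <- c(FEATURE_NAMES, "(Intercept)")
  if (is.null(names(alpha)) && length(alpha) == 9L) names(alpha) <- expected
  if (!setequal(names(alpha), expected))
    stop_varfit("alpha must have names ", paste(expected, collapse = ", "))
  if (any(!is.finite(alpha))) stop_varfit("non-finite alpha")
  base::structure(list(alpha = alpha[expected], beta = beta, gamma = gamma,
                       provenance = provenance, version = "1.0"),
                  class = "varfit_coefficients")
}

#' @export
print.varfit_coefficients <- function(x, ...) {
  cat("Variant-fitness model coefficients (", x$provenance, ")\n", sep = "")
  print(round(x$alpha, 4))
  invisible(x)
}

#' Write coefficients to a versioned JSON file
#'
#' @param coef a [varfit_coefficients()] object (or a fitted [varfit()]
#'   model, whose alpha part is taken).
#' @param path output path.
#' @param ... passed to [varfit_coefficients()] when `coef` is a fit.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coef, path, ...) {
  if (inherits(coef, "varfit")) coef <- varfit_coefficients(coef$alpha, ...)
  payload <- list(format = "varfit-coefficients", version = coef$version,
                  provenance = coef$provenance,
                  alpha = as.list(coef$alpha),
                  beta = if (!is.null(coef$beta)) as.list(coef$beta),
                  gamma = if (!is.null(coef$gamma)) as.list(coef$gamma))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read coefficients written by [write_coefficients()]
#'
#' @param path JSON path.
#' @return a [varfit_coefficients()] object.
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "varfit-coefficients"))
    stop_varfit("not a coefficients file: ", path)
  alpha <- unlist(x$alpha)
  varfit_coefficients(alpha,
                      beta = if (!is.null(x$beta)) unlist(x$beta),
                      gamma = if (!is.null(x$gamma)) unlist(x$gamma),
                      provenance = x$provenance %||% "unspecified")
}

#' Score the full single-site mutational landscape of a protein
#'
#' Enumerates all 19 substitutions at every query position, assembles the
#' eight features, median-imputes absent members, applies the linear
#' model, splits structural and evolutionary contributions and attaches
#' the three z-scores.  This is the end-to-end prediction workflow behind
#' the command-line `predict` subcommand.
#'
#' @param msa an [`msa`][read_msa]; the query row (gaps removed) defines
#'   the protein.
#' @param coefficients a [varfit_coefficients()] or fitted [varfit()].
#' @param structure optional [`pdb_structure`][read_structure] for RSA;
#'   accessibility is computed on the full complex.
#' @param chain chain of `structure` carrying the query protein.
#' @param external optional [`feature_table`][load_feature_table].
#' @param potts optional pre-fitted `potts_model`; default: fitted on the
#'   fly from the alignment.
#' @param theta pseudocount of the frequency model.
#' @param sasa_n_points quadrature points for [compute_sasa()].
#' @return a score table: one row per variant with `position`, `wt`,
#'   `mt`, `RSA`, the remaining features, and the last four columns
#'   `score`, `Z`, `Z_evo`, `Z_str`.
#' @export
score_landscape <- function(msa, coefficients, structure = NULL,
                            chain = NULL, external = NULL, potts = NULL,
                            theta = 0.01, sasa_n_points = 960L) {
  if (inherits(coefficients, "varfit"))
    coefficients <- varfit_coefficients(coefficients$alpha)
  q <- msa_query(msa)
  if (any(q == GAP))
    stop_varfit("query row of the alignment must be ungapped")
  L <- length(q)
  if (is.null(potts)) potts <- fit_potts_plm(msa)
  rsa_by_position <- NULL
  if (!is.null(structure)) {
    if (is.null(chain)) chain <- attr(structure, "chains")[1L]
    smap <- map_structure_to_sequence(structure, chain, q)
    sasa <- compute_sasa(structure, n_points = sasa_n_points)
    sasa <- relative_solvent_accessibility(sasa)
    skey <- paste(sasa$chain, sasa$resno, sasa$insert, sep = "|")
    mkey <- paste(chain, smap$resno, smap$insert, sep = "|")
    rsa_by_position <- sasa$rsa[match(mkey, skey)]
    rsa_by_position[!smap$mapped] <- NA_real_
  }
  variants <- data.frame(
    position = rep(seq_len(L), each = 19L),
    wt = rep(q, each = 19L),
    mt = unlist(lapply(q, function(a) setdiff(AA20, a))),
    stringsAsFactors = FALSE)
  fv <- assemble_features(variants, msa, potts = potts,
                          rsa_by_position = rsa_by_position,
                          external = external, theta = theta)
  # features absent for every variant (e.g. no external table, no
  # structure) contribute zero to every score instead of blocking the run;
  # their missing_* flags stay TRUE so the absence is visible downstream
  for (f in FEATURE_NAMES) {
    if (all(is.na(fv[[f]]))) fv[[f]] <- 0
  }
  fv <- impute_missing(fv)
  fv$score <- linear_score(fv, coefficients)
  fv <- cbind(fv, decompose_score(fv, coefficients))
  fv <- zscores(fv)
  flags <- grep("^missing_", names(fv), value = TRUE)
  fv[, c("position", "wt", "mt", FEATURE_NAMES, flags, "STR", "EVO",
         "score", "Z", "Z_evo", "Z_str")]
}
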