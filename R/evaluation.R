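#' Remove hyper-complementing variants from a benchmark set
#'
#' Variants whose experimental fitness is strictly above the cutoff
#' (default 1.36) are discarded: such hyper-complementing variants in
#' yeast assays are often disadvantageous in human and are excluded from
#' evaluation.  The removal is logged in the `filter_log` attribute.
#'
#' @param set data.frame with an `exp` column of experimental fitness.
#' @param cutoff fitness cutoff; strictly-greater values are removed.
#' @return the filtered data.frame.
#' @export
filter_hypercomplementing <- function(set, cutoff = 1.36) {
  if (!is.finite(cutoff)) cutoff <- Inf
  keep <- set$exp <= cutoff
  out <- set[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("all variants removed by the hyper-complementing filter",
            call. = FALSE)
  log <- c(attr(set, "filter_log"),
           sprintf("hyper-complementing filter (> %g): removed %d of %d",
                   cutoff, sum(!keep), length(keep)))
  base::structure(out, filter_log = log)
}

#' Floor negative fitness and drop high-uncertainty variants
#'
#' Negative experimental fitness values are set to zero; variants whose
#' standard error strictly exceeds `se_max` (default 0.3) are removed.
#' Without an `se` column the flooring still applies and the exclusion is
#' skipped with a warning.
#'
#' @param set data.frame with `exp` and optionally `se` columns.
#' @param se_max standard-error threshold; strictly-greater values are
#'   removed.
#' @return the filtered data.frame (with `exp` floored).
#' @export
filter_floor_and_se <- function(set, se_max = 0.3) {
  prior_log <- attr(set, "filter_log")
  n0 <- nrow(set)
  floored <- sum(set$exp < 0)
  set$exp[set$exp < 0] <- 0
  removed <- 0L
  if ("se" %in% names(set)) {
    keep <- is.na(set$se) | set$se <= se_max
    removed <- sum(!keep)
    set <- set[keep, , drop = FALSE]
  } else {
    warning("no 'se' column: standard-error exclusion skipped",
            call. = FALSE)
  }
  log <- c(prior_log,
           sprintf("floor/SE filter (SE > %g): floored %d, removed %d of %d",
                   se_max, floored, removed, n0))
  base::structure(set, filter_log = log)
}

#' Correlation and deviation metrics between predictions and experiment
#'
#' Kendall rank correlation (tau-b, tie-corrected), Spearman rank
#' correlation (mid-rank ties), Pearson correlation, and the root mean
#' squared deviation.
#'
#' @param pred,exp numeric vectors of equal length (at least 3).
#' @return named list `kendall`, `spearman`, `pearson`, `rmsd`, `n`.
#' @export
correlation_metrics <- function(pred, exp) {
  if (length(pred) != length(exp)) stop_varfit("length mismatch")
  if (length(pred) < 3L) stop_varfit("need at least 3 pairs")
  if (anyNA(pred) || anyNA(exp)) stop_varfit("missing values")
  if (stats::sd(pred) == 0 || stats::sd(exp) == 0)
    stop_varfit("constant vector: correlations undefined")
  list(kendall = stats::cor(pred, exp, method = "kendall"),
       spearman = stats::cor(pred, exp, method = "spearman"),
       pearson = stats::cor(pred, exp, method = "pearson"),
       rmsd = sqrt(mean((pred - exp)^2)),
       n = length(pred))
}

check_labels <- function(labels) {
  bad <- setdiff(unique(labels), c("pathogenic", "benign"))
  if (length(bad) > 0L)
    stop_varfit("labels must be 'pathogenic' or 'benign'; got: ",
                paste(bad, collapse = ", "))
  if (!any(labels == "pathogenic") || !any(labels == "benign"))
    stop_varfit("both classes must be non-empty")
}

#' Threshold classification metrics for pathogenicity
#'
#' Scores are on the fitness scale, so a prediction strictly below the
#' threshold calls the variant pathogenic (low fitness = deleterious).
#' Sensitivity is recall on the pathogenic class, specificity recall on
#' the benign class, and BACC their mean.
#'
#' @param pred numeric scores.
#' @param labels character vector in `{"pathogenic", "benign"}`.
#' @param threshold decision threshold (default 0.5).
#' @return named list `sensitivity`, `specificity`, `bacc`, `threshold`.
#' @export
classification_metrics <- function(pred, labels, threshold = 0.5) {
  if (length(pred) != length(labels)) stop_varfit("length mismatch")
  check_labels(labels)
  call_path <- pred < threshold
  sens <- mean(call_path[labels == "pathogenic"])
  spec <- mean(!call_path[labels == "benign"])
  list(sensitivity = sens, specificity = spec, bacc = (sens + spec) / 2,
       threshold = threshold)
}

#' Area under the ROC curve
#'
#' Threshold-independent classification performance with
#' pathogenic-as-positive and lower-score-is-more-pathogenic orientation.
#' Computed by the rank (Mann-Whitney) formulation, which handles ties by
#' mid-ranks and equals trapezoidal integration of the ROC curve.
#'
#' @inheritParams classification_metrics
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(pred, labels) {
  if (length(pred) != length(labels)) stop_varfit("length mismatch")
  check_labels(labels)
  # orient so that larger value = more pathogenic
  x <- -pred
  r <- rank(x)
  n1 <- sum(labels == "pathogenic")
  n0 <- sum(labels == "benign")
  U <- sum(r[labels == "pathogenic"]) - n1 * (n1 + 1) / 2
  U / (n1 * n0)
}

#' Full evaluation report for one prediction column
#'
#' Applies the requested benchmark filters, then computes all correlation
#' metrics against experimental fitness and, when clinical labels are
#' present, the classification metrics and AUC-ROC.
#'
#' @param set data.frame with columns `pred`, `exp`, optional `se` and
#'   `label`.
#' @param hyper_cutoff hyper-complementing cutoff, or `NULL` to skip.
#' @param floor_and_se apply [filter_floor_and_se()]?
#' @param se_max standard-error threshold for that filter.
#' @param threshold classification threshold.
#' @param polarity `+1` if larger predictions mean fitter (the fitness
#'   convention), `-1` for predictors with the opposite orientation.
#' @return object of class `metrics_report` (named list including the
#'   filter log).
#' @export
evaluate_predictions <- function(set, hyper_cutoff = 1.36,
                                 floor_and_se = FALSE, se_max = 0.3,
                                 threshold = 0.5, polarity = 1) {
  if (!all(c("pred", "exp") %in% names(set)))
    stop_varfit("set needs 'pred' and 'exp' columns")
  set$pred <- polarity * set$pred
  if (!is.null(hyper_cutoff)) set <- filter_hypercomplementing(set, hyper_cutoff)
  if (floor_and_se) set <- filter_floor_and_se(set, se_max)
  out <- correlation_metrics(set$pred, set$exp)
  if ("label" %in% names(set) && any(!is.na(set$label))) {
    lab <- set[!is.na(set$label), , drop = FALSE]
    cls <- classification_metrics(lab$pred, lab$label, threshold)
    out <- c(out, cls, list(auc_roc = auc_roc(lab$pred, lab$label)))
  }
  out$filter_log <- attr(set, "filter_log") %||% character(0)
  base::structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Evaluation report (n =", x$n, ")\n")
  cat(sprintf("  Kendall %.3f  Spearman %.3f  Pearson %.3f  RMSD %.3f\n",
              x$kendall, x$spearman, x$pearson, x$rmsd))
  if (!is.null(x$bacc))
    cat(sprintf("  Sens %.3f  Spec %.3f  BACC %.3f  AUC-ROC %.3f\n",
                x$sensitivity, x$specificity, x$bacc, x$auc_roc))
  for (l in x$filter_log) cat("  [filter] ", l, "\n", sep = "")
  invisible(x)
}
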