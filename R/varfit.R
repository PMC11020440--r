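#' Fit the linear variant-fitness model
#'
#' Fits, by least squares, the linear combination of the eight per-variant
#' features that predicts experimental fitness:
#' \deqn{\hat y = \alpha_1\,\mathrm{RSA} + \alpha_2\,\mathrm{PoP} +
#'   \alpha_3\,\mathrm{MAE} + \alpha_4\,\mathrm{SNP} +
#'   \alpha_5\,\mathrm{PVS} + \alpha_6\,\mathrm{CI} +
#'   \alpha_7\,\mathrm{LOR} + \alpha_8\,\mathrm{PYF} + \alpha_9.}
#' The fitness scale follows the deep-mutational-scanning convention:
#' 1 means wild-type-like, 0 or below non-functional, above 1 fitter than
#' the wild type.  The summary reports the standardized-coefficient ratio
#' of the evolutionary block (PVS, CI, LOR, PYF) to the structural block
#' (PoP, MAE, SNP), the model's interpretability diagnostic.
#'
#' @param data data.frame containing the eight feature columns
#'   (`RSA`, `PoP`, `MAE`, `SNP`, `PVS`, `CI`, `LOR`, `PYF`) and the
#'   response named by `response`.  Features must be complete; run
#'   [impute_missing()] first if needed.
#' @param method `"ols"` for plain least squares (errors on a
#'   rank-deficient design) or `"ridge"` for an L2-penalized fit.
#' @param lambda ridge penalty (ignored for `"ols"`); default `1e-6`,
#'   a numerical floor rather than a tuned shrinkage.
#' @param response name of the response column; default `"fitness"`.
#' @return an object of class `varfit` with components `alpha` (the nine
#'   named coefficients, intercept last), `se`, `sigma`, `fitted.values`,
#'   `residuals`, `std_alpha`, `evo_str_ratio`, `n`, `method`, `call`.
#' @examples
#' train <- make_synthetic_dms(n = 200, seed = 7)
#' fit <- varfit(train)
#' coef(fit)
#' @seealso [predict.varfit()], [zscores()], [score_landscape()]
#' @export
varfit <- function(data, method = c("ols", "ridge"), lambda = 1e-6,
                   response = "fitness") {
  method <- match.arg(method)
  missing_cols <- setdiff(c(FEATURE_NAMES, response), names(data))
  if (length(missing_cols) > 0L)
    stop_varfit("training data lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  X <- as.matrix(data[, FEATURE_NAMES, drop = FALSE])
  y <- data[[response]]
  if (anyNA(X))
    stop_varfit("features contain missing values; run impute_missing() first")
  if (anyNA(y) || any(!is.finite(y))) stop_varfit("non-finite fitness values")
  n <- nrow(X)
  p <- ncol(X) + 1L
  if (n < p) stop_varfit("need at least ", p, " rows to fit ", p,
                         " coefficients; got ", n)
  Xd <- cbind(X, `(Intercept)` = 1)
  if (method == "ols") {
    qrX <- qr(Xd)
    if (qrX$rank < p)
      stop_varfit("design matrix is rank-deficient (rank ", qrX$rank,
                  " < ", p, "); refit with method = \"ridge\"")
    alpha <- qr.coef(qrX, y)
    fitted <- unname(drop(Xd %*% alpha))
    res <- y - fitted
    df <- n - p
    sigma <- sqrt(sum(res^2) / df)
    XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
    se <- sigma * sqrt(diag(XtXinv))
  } else {
    pen <- diag(c(rep(lambda, p - 1L), 0))   # intercept unpenalized
    A <- crossprod(Xd) + pen
    alpha <- drop(solve(A, crossprod(Xd, y)))
    fitted <- unname(drop(Xd %*% alpha))
    res <- y - fitted
    df <- n - p
    sigma <- sqrt(sum(res^2) / max(df, 1L))
    Ainv <- solve(A)
    covb <- sigma^2 * Ainv %*% crossprod(Xd) %*% Ainv
    se <- sqrt(diag(covb))
  }
  names(alpha) <- names(se) <- c(FEATURE_NAMES, "(Intercept)")
  sds <- apply(X, 2L, stats::sd)
  std_alpha <- alpha[FEATURE_NAMES] * sds
  ratio <- sum(abs(std_alpha[EVO_FEATURES])) / sum(abs(std_alpha[STR_FEATURES]))
  base::structure(
    list(alpha = alpha, se = se, sigma = sigma, df.residual = df,
         fitted.values = fitted, residuals = res, y = y,
         std_alpha = std_alpha, evo_str_ratio = ratio, n = n,
         method = method, lambda = if (method == "ridge") lambda else NULL,
         feature_sd = sds, call = match.call()),
    class = "varfit")
}

#' @export
print.varfit <- function(x, digits = 4, ...) {
  cat("Linear variant-fitness model (", x$method, ", n = ", x$n, ")\n\n",
      sep = "")
  print(round(x$alpha, digits))
  cat(sprintf("\nResidual sd: %.*f;  evolutionary/structural weight ratio: %.2f\n",
              digits, x$sigma, x$evo_str_ratio))
  invisible(x)
}

#' @export
coef.varfit <- function(object, ...) object$alpha

#' @export
residuals.varfit <- function(object, ...) object$residuals

#' @export
fitted.varfit <- function(object, ...) object$fitted.values

#' @export
summary.varfit <- function(object, ...) {
  tab <- cbind(Estimate = object$alpha, `Std. Error` = object$se,
               `t value` = object$alpha / object$se)
  base::structure(list(coefficients = tab, sigma = object$sigma,
                       df.residual = object$df.residual,
                       std_alpha = object$std_alpha,
                       evo_str_ratio = object$evo_str_ratio,
                       n = object$n, method = object$method,
                       call = object$call),
                  class = "summary.varfit")
}

#' @export
print.summary.varfit <- function(x, digits = 4, ...) {
  cat("Linear variant-fitness model — ", x$method, " fit, n = ", x$n,
      "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nResidual sd %.4g on %d degrees of freedom\n",
              x$sigma, x$df.residual))
  cat("Standardized coefficients (feature sd units):\n")
  print(round(x$std_alpha, digits))
  cat(sprintf("Evolutionary block / structural block weight ratio: %.2f\n",
              x$evo_str_ratio))
  invisible(x)
}

#' Predict fitness scores for new variants
#'
#' @param object a fitted [varfit()] model.
#' @param newdata data.frame with the eight feature columns (complete).
#' @param ... unused.
#' @return numeric vector of raw (unclamped) fitness scores.
#' @export
predict.varfit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  linear_score(newdata, object$alpha)
}

#' Simulate fitness responses from a fitted model
#'
#' Draws new response vectors as fitted values plus Gaussian noise with
#' the residual standard deviation.
#'
#' @param object a fitted [varfit()] model.
#' @param nsim number of response vectors.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.varfit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() object$fitted.values +
    stats::rnorm(object$n, sd = object$sigma)
  sims <- if (is.null(seed)) replicate(nsim, draw())
  else with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.varfit <- function(x, ...) {
  graphics::plot(x$fitted.values, x$y,
                 xlab = "predicted fitness", ylab = "observed fitness",
                 main = "Variant-fitness model fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
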