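## Potts model over aligned positions: q = 21 states (gap included), fields
## h[i, a] and couplings J[a, b, i, j] with the symmetry J[a,b,i,j] =
## J[b,a,j,i].  Statistical energy E(s) = -sum_i h_i(s_i) -
## sum_{i<j} J_ij(s_i, s_j); low energy = favourable sequence.

msa_to_int <- function(msa, alphabet = AA21) {
  mat <- matrix(match(msa, alphabet), nrow = nrow(msa))
  if (anyNA(mat)) stop_varfit("sequence contains states outside the alphabet")
  mat
}

#' Construct a Potts model from explicit parameters
#'
#' @param h N x q field matrix.
#' @param J q x q x N x N coupling array with `J[a,b,i,j] = J[b,a,j,i]`.
#' @param alphabet state characters; default the first `q` of the
#'   21-state alphabet.
#' @return a `potts_model`.
#' @export
new_potts_model <- function(h, J, alphabet = NULL) {
  N <- nrow(h); q <- ncol(h)
  stopifnot(length(dim(J)) == 4L, all(dim(J) == c(q, q, N, N)))
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j) {
    if (max(abs(J[, , i, j] - t(J[, , j, i]))) > 1e-9)
      stop_varfit("couplings violate J[a,b,i,j] = J[b,a,j,i]")
  }
  if (is.null(alphabet)) alphabet <- AA21[seq_len(q)]
  base::structure(list(h = h, J = J, N = N, q = q, alphabet = alphabet,
                       lambda_h = NA_real_, lambda_J = NA_real_,
                       reweight_threshold = NA_real_, m_eff = NA_real_,
                       diagnostics = NULL),
                  class = "potts_model")
}

#' Sequence reweighting for direct coupling analysis
#'
#' Standard redundancy correction: the weight of row `k` is the reciprocal
#' of the number of rows (including itself) whose fractional identity to
#' row `k` is at least `threshold`.
#'
#' @param msa an [`msa`][read_msa] object.
#' @param threshold identity fraction in (0, 1]; default 0.8.
#' @return list with `w` (per-row weights in (0, 1]) and `m_eff`
#'   (effective depth, `sum(w)`).
#' @export
sequence_weights <- function(msa, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop_varfit("threshold must be in (0, 1]")
  X <- msa_to_int(msa)
  m <- nrow(X); N <- ncol(X)
  # pairwise identity via per-state indicator cross-products
  sim <- matrix(0L, m, m)
  for (a in sort(unique(as.vector(X)))) {
    Ia <- (X == a) * 1L
    sim <- sim + tcrossprod(Ia)
  }
  counts <- rowSums(sim / N >= threshold)
  w <- 1 / counts
  list(w = w, m_eff = sum(w))
}

#' Fit a Potts model by pseudo-likelihood maximization
#'
#' Asymmetric per-site pseudo-likelihood: for each position `r` the
#' conditional distribution of its state given the rest of the sequence is
#' a multinomial logistic model with parameters `h_r` and `J_r,j`; each
#' site's weighted, L2-regularized negative log pseudo-likelihood is
#' minimized independently by L-BFGS-B from a zero start, couplings are
#' symmetrized by averaging the two per-site estimates, and the result is
#' reported in the zero-sum gauge.
#'
#' @param msa an [`msa`][read_msa] object with at least 2 rows.
#' @param weights optional [sequence_weights()] result; default: computed
#'   at threshold 0.8.
#' @param lambda_h,lambda_J L2 penalties on fields and couplings.  Defaults
#'   `0.01` and `0.01 * (N - 1)` follow common plmDCA-style scaling.
#' @param q alphabet size; default 21 (gap as an ordinary state).
#' @param pgtol projected-gradient tolerance of the optimizer.
#' @param maxit iteration budget per site; exceeding it is an error.
#' @return an object of class `potts_model`: `h` (N x q), `J`
#'   (q x q x N x N array in zero-sum gauge), `alphabet`, hyperparameters
#'   and per-site convergence diagnostics.
#' @export
fit_potts_plm <- function(msa, weights = NULL, lambda_h = 0.01,
                          lambda_J = 0.01 * (ncol(msa) - 1), q = 21L,
                          pgtol = 1e-5, maxit = 1000L) {
  if (nrow(msa) < 2L) stop_varfit("need at least 2 sequences to fit")
  if (!is.finite(lambda_h) || lambda_h <= 0 ||
      !is.finite(lambda_J) || lambda_J <= 0)
    stop_varfit("regularization strengths must be finite and > 0")
  alphabet <- AA21[seq_len(q)]
  X <- msa_to_int(msa, alphabet)
  m <- nrow(X); N <- ncol(X)
  if (is.null(weights)) weights <- sequence_weights(msa)
  w <- weights$w
  onehot <- lapply(seq_len(N), function(j) {
    M <- matrix(0, m, q)
    M[cbind(seq_len(m), X[, j])] <- 1
    M
  })

  h <- matrix(0, N, q)
  Jhat <- array(0, dim = c(q, q, N, N))   # Jhat[a,b,r,j]: site-r estimate
  diagnostics <- vector("list", N)

  for (r in seq_len(N)) {
    others <- setdiff(seq_len(N), r)
    npar <- q + q * q * length(others)
    y <- X[, r]
    fn_gr <- function(par) {
      hr <- par[seq_len(q)]
      Jr <- array(par[-seq_len(q)], dim = c(q, q, length(others)))
      E <- matrix(hr, m, q, byrow = TRUE)
      for (k in seq_along(others))
        E <- E + t(Jr[, X[, others[k]], k])
      Emax <- apply(E, 1L, max)
      P <- exp(E - Emax)
      P <- P / rowSums(P)
      nll <- -sum(w * (E[cbind(seq_len(m), y)] - Emax - log(rowSums(exp(E - Emax))))) +
        lambda_h * sum(hr^2) + lambda_J * sum(Jr^2)
      D <- w * P
      D[cbind(seq_len(m), y)] <- D[cbind(seq_len(m), y)] - w
      gh <- colSums(D) + 2 * lambda_h * hr
      gJ <- array(0, dim = c(q, q, length(others)))
      for (k in seq_along(others))
        gJ[, , k] <- crossprod(D, onehot[[others[k]]])
      gJ <- gJ + 2 * lambda_J * Jr
      list(value = nll, gradient = c(gh, as.vector(gJ)))
    }
    cache <- new.env()
    fn <- function(par) {
      res <- fn_gr(par)
      assign("g", res$gradient, envir = cache)
      res$value
    }
    gr <- function(par) get("g", envir = cache)
    opt <- stats::optim(rep(0, npar), fn, gr, method = "L-BFGS-B",
                        control = list(pgtol = pgtol, maxit = maxit))
    if (opt$convergence != 0L)
      stop_varfit("pseudo-likelihood optimization did not converge at site ",
                  r, " (code ", opt$convergence, ": ", opt$message, ")")
    h[r, ] <- opt$par[seq_len(q)]
    Jr <- array(opt$par[-seq_len(q)], dim = c(q, q, length(others)))
    for (k in seq_along(others)) Jhat[, , r, others[k]] <- Jr[, , k]
    diagnostics[[r]] <- list(value = opt$value, counts = opt$counts)
  }

  # symmetrize: average the two asymmetric estimates of each coupling
  J <- array(0, dim = c(q, q, N, N))
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
    J[, , i, j] <- (Jhat[, , i, j] + t(Jhat[, , j, i])) / 2

  model <- structure(list(h = h, J = J, N = N, q = q, alphabet = alphabet,
                          lambda_h = lambda_h, lambda_J = lambda_J,
                          reweight_threshold = 0.8, m_eff = weights$m_eff,
                          diagnostics = diagnostics),
                     class = "potts_model")
  zero_sum_gauge(model)
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("Potts model: %d positions, %d states, M_eff = %.1f\n",
              x$N, x$q, x$m_eff %||% NA_real_))
  invisible(x)
}

#' Transform a Potts model to the zero-sum gauge
#'
#' Removes gauge freedom so that fields and couplings sum to zero over
#' states: for every `i`, `sum_a h_i(a) = 0`, and for every pair and state
#' `b`, `sum_a J_ij(a, b) = 0`.  Sequence energies change only by a
#' sequence-independent constant, so all energy differences are preserved.
#'
#' @param model a `potts_model`.
#' @return the gauge-fixed `potts_model`.
#' @export
zero_sum_gauge <- function(model) {
  h <- model$h; J <- model$J; N <- model$N; q <- model$q
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j) {
    Jij <- J[, , i, j]
    rm_ <- rowMeans(Jij); cm_ <- colMeans(Jij); mm <- mean(Jij)
    # field absorbs the row means of every coupling touching site i
    h[i, ] <- h[i, ] + (rm_ - mm)
    J[, , i, j] <- Jij - outer(rm_, rep(1, q)) - outer(rep(1, q), cm_) + mm
  }
  h <- h - rowMeans(h)
  model$h <- h; model$J <- J
  model
}

#' Apply an arbitrary gauge transformation to a Potts model
#'
#' Shifts each coupling by per-state functions and compensates in the
#' fields so that every sequence energy is unchanged.  Used to verify
#' gauge invariance of energy differences.
#'
#' @param model a `potts_model`.
#' @param g,gt lists (or NULL for random draws) of per-pair state shifts.
#' @param seed seed for random shifts.
#' @return a gauge-transformed `potts_model` with identical energies.
#' @export
gauge_transform <- function(model, g = NULL, gt = NULL, seed = 1L) {
  N <- model$N; q <- model$q
  if (is.null(g) || is.null(gt)) {
    with_seed(seed, {
      g <- array(stats::rnorm(q * N * N), dim = c(q, N, N))
      gt <- array(stats::rnorm(q * N * N), dim = c(q, N, N))
    })
  }
  h <- model$h; J <- model$J
  for (i in seq_len(N - 1L)) for (j in seq(i + 1L, N)) {
    J[, , i, j] <- J[, , i, j] + outer(g[, i, j], rep(1, q)) +
      outer(rep(1, q), gt[, i, j])
    J[, , j, i] <- t(J[, , i, j])
    h[i, ] <- h[i, ] - g[, i, j]
    h[j, ] <- h[j, ] - gt[, i, j]
  }
  model$h <- h; model$J <- J
  model
}

#' Save a Potts model to a self-describing JSON container
#'
#' The container carries a format tag, version, shapes, hyperparameters
#' and the flattened parameters (column-major), so it can be validated
#' and reloaded exactly.
#'
#' @param model a `potts_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_potts_model <- function(model, path) {
  payload <- list(format = "varfit-potts", version = "1.0",
                  N = model$N, q = model$q,
                  alphabet = paste(model$alphabet, collapse = ""),
                  lambda_h = model$lambda_h, lambda_J = model$lambda_J,
                  reweight_threshold = model$reweight_threshold,
                  m_eff = model$m_eff,
                  h = as.vector(model$h), J = as.vector(model$J))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a Potts model written by [write_potts_model()]
#'
#' @param path JSON path.
#' @return a `potts_model`.
#' @export
read_potts_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "varfit-potts"))
    stop_varfit("not a Potts model container: ", path)
  N <- x$N; q <- x$q
  model <- new_potts_model(matrix(x$h, N, q),
                           array(x$J, dim = c(q, q, N, N)),
                           alphabet = strsplit(x$alphabet, "")[[1L]])
  model$lambda_h <- x$lambda_h; model$lambda_J <- x$lambda_J
  model$reweight_threshold <- x$reweight_threshold; model$m_eff <- x$m_eff
  model
}

#' Statistical energy of an aligned sequence under a Potts model
#'
#' \deqn{E(s) = -\sum_i h_i(s_i) - \sum_{i<j} J_{ij}(s_i, s_j).}
#'
#' @param model a `potts_model`.
#' @param seq character vector (or single string) of length `N` over the
#'   model alphabet.
#' @return scalar energy.
#' @export
sequence_energy <- function(model, seq) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(seq) != model$N)
    stop_varfit("sequence length ", length(seq),
                " does not match model size ", model$N)
  s <- match(seq, model$alphabet)
  if (anyNA(s)) stop_varfit("sequence contains states outside the alphabet")
  N <- model$N
  e <- -sum(model$h[cbind(seq_len(N), s)])
  for (i in seq_len(N - 1L)) for (j in seq(i + 1L, N))
    e <- e - model$J[s[i], s[j], i, j]
  e
}

#' Potts statistical-energy change of a variant
#'
#' The feature score of a substitution is `E(wt) - E(mt)`, evaluated
#' incrementally in O(N): a mutation that raises the statistical energy
#' (unfavourable in the coevolutionary model) gives a negative score,
#' matching the convention that negative means fitness loss.
#'
#' @param model a `potts_model`.
#' @param wt_seq aligned wild-type sequence (character vector or string).
#' @param variant a [variant()]; its position indexes `wt_seq`.
#' @return scalar score with logical attribute `gap_column` set when the
#'   wild-type state at the position is a gap (score 0).
#' @export
variant_delta_fitness <- function(model, wt_seq, variant) {
  if (length(wt_seq) == 1L && nchar(wt_seq) > 1L)
    wt_seq <- strsplit(wt_seq, "", fixed = TRUE)[[1L]]
  if (length(wt_seq) != model$N)
    stop_varfit("wild-type sequence length does not match model size")
  i <- variant$position
  if (i < 1L || i > model$N) stop_varfit("variant position out of bounds")
  if (wt_seq[i] == GAP) return(structure(0, gap_column = TRUE))
  if (wt_seq[i] != variant$wt)
    stop_varfit("wild-type mismatch at position ", i)
  s <- match(wt_seq, model$alphabet)
  if (anyNA(s)) stop_varfit("sequence contains states outside the alphabet")
  a_wt <- match(variant$wt, model$alphabet)
  a_mt <- match(variant$mt, model$alphabet)
  if (is.na(a_mt)) stop_varfit("mutant state outside the model alphabet")
  d <- model$h[i, a_mt] - model$h[i, a_wt]
  for (j in seq_len(model$N)) if (j != i)
    d <- d + model$J[a_mt, s[j], i, j] - model$J[a_wt, s[j], i, j]
  structure(d, gap_column = FALSE)
}
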