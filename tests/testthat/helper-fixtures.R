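# shared fixtures and independent oracles for the test suite

# random small alignment (query ungapped) built directly, not via the
# package generators, so generator and feature code are tested separately
random_msa <- function(m, N, gap_prob = 0.15, seed = NULL) {
  draw <- function() {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    q <- sample(aa, N, replace = TRUE)
    rows <- matrix(sample(c(aa, "-"), m * N, replace = TRUE,
                          prob = c(rep((1 - gap_prob) / 20, 20), gap_prob)),
                   m, N)
    new_msa_from_strings(apply(rbind(q, rows), 1, paste, collapse = ""))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

AA20_FIX <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# brute-force per-column regularized frequencies (direct formula)
oracle_frequencies <- function(msa, theta) {
  states <- c(AA20_FIX, "-")
  m <- nrow(msa); N <- ncol(msa)
  f_col <- matrix(NA_real_, N, 21, dimnames = list(NULL, states))
  for (i in seq_len(N)) for (a in states)
    f_col[i, a] <- (sum(msa[, i] == a) / m) * (1 - theta) + theta / 21
  f_global <- sapply(states, function(a)
    (sum(msa == a) / (m * N)) * (1 - theta) + theta / 21)
  list(f_col = f_col, f_global = f_global)
}

# uniform weights for exact iid samples (no redundancy correction)
uniform_weights <- function(m) list(w = rep(1, m), m_eff = m)

# random complete feature table on realistic scales
random_features <- function(n, seed = NULL) {
  draw <- function() data.frame(
    RSA = runif(n, 0, 110), PoP = rnorm(n), MAE = rnorm(n),
    SNP = rnorm(n), PVS = rnorm(n), CI = abs(rnorm(n, 0.3, 0.2)),
    LOR = rnorm(n), PYF = rnorm(n))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

random_alpha <- function(seed = NULL) {
  draw <- function() {
    a <- rnorm(9)
    names(a) <- c("RSA", "PoP", "MAE", "SNP", "PVS", "CI", "LOR", "PYF",
                  "(Intercept)")
    a
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
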