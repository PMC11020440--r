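test_that("sequence weights follow the identity-count definition", {
  aln <- new_msa_from_strings(rep("ACDEF", 4))
  w <- sequence_weights(aln)
  expect_equal(w$w, rep(1 / 4, 4))
  expect_equal(w$m_eff, 1)
  # pairwise distinct rows: all weights 1
  aln2 <- new_msa_from_strings(c("ACDEF", "GHIKL", "MNPQR", "STVWY"))
  w2 <- sequence_weights(aln2)
  expect_equal(w2$w, rep(1, 4))
  expect_equal(w2$m_eff, 4)
  # one duplicated pair among distinct rows
  aln3 <- new_msa_from_strings(c("ACDEF", "ACDEF", "GHIKL", "MNPQR", "STVWY"))
  w3 <- sequence_weights(aln3)
  expect_equal(w3$w, c(0.5, 0.5, 1, 1, 1))
})

test_that("sequence energy: zero model, additive fields, and Boltzmann", {
  h <- matrix(0, 3, 3)
  J <- array(0, dim = c(3, 3, 3, 3))
  zero <- new_potts_model(h, J)
  expect_equal(sequence_energy(zero, c("A", "C", "D")), 0)
  hm <- withr::with_seed(2, matrix(rnorm(9), 3, 3))
  fieldonly <- new_potts_model(hm, J)
  s <- c("C", "A", "D")
  idx <- match(s, fieldonly$alphabet)
  expect_equal(sequence_energy(fieldonly, s),
               -sum(hm[cbind(1:3, idx)]))
  expect_error(sequence_energy(zero, c("A", "C")), "length")
  # exact-mode sampler probabilities equal exp(-E)/Z over all 27 states
  sim <- sample_potts_msa(m = 10, N = 3, q = 3, seed = 7)
  E <- apply(sim$states, 1, function(st)
    sequence_energy(sim$model, sim$model$alphabet[st]))
  p <- exp(-(E - min(E))); p <- p / sum(p)
  expect_equal(p, sim$probs, tolerance = 1e-10)
})

test_that("variant energy change: identity, field-only form, resummation", {
  sim <- sample_potts_msa(m = 5, N = 4, q = 4, seed = 3)
  model <- sim$model
  wt_seq <- sim$msa[1, ]
  v0 <- structure(list(position = 2L, wt = wt_seq[2], mt = wt_seq[2]),
                  class = "variant")
  expect_equal(as.numeric(variant_delta_fitness(model, wt_seq, v0)), 0)
  # J = 0: score reduces to the field difference
  fieldonly <- model
  fieldonly$J[] <- 0
  alt <- setdiff(model$alphabet, wt_seq[2])[1]
  v <- structure(list(position = 2L, wt = wt_seq[2], mt = alt),
                 class = "variant")
  iw <- match(wt_seq[2], model$alphabet); im <- match(alt, model$alphabet)
  expect_equal(as.numeric(variant_delta_fitness(fieldonly, wt_seq, v)),
               fieldonly$h[2, im] - fieldonly$h[2, iw])
  # incremental evaluation equals full re-summation for every variant
  for (pos in 1:4) for (mt in setdiff(model$alphabet, wt_seq[pos])) {
    vv <- structure(list(position = pos, wt = wt_seq[pos], mt = mt),
                    class = "variant")
    mt_seq <- wt_seq; mt_seq[pos] <- mt
    expect_equal(as.numeric(variant_delta_fitness(model, wt_seq, vv)),
                 sequence_energy(model, wt_seq) -
                   sequence_energy(model, mt_seq),
                 tolerance = 1e-10)
  }
})

test_that("variant scores are gauge invariant", {
  sim <- sample_potts_msa(m = 5, N = 4, q = 4, seed = 13)
  model <- sim$model
  wt_seq <- sim$msa[1, ]
  transformed <- gauge_transform(model, seed = 99)
  # the transformation really moved the parameters
  expect_gt(max(abs(transformed$J - model$J)), 0.1)
  for (pos in 1:4) for (mt in setdiff(model$alphabet, wt_seq[pos])) {
    vv <- structure(list(position = pos, wt = wt_seq[pos], mt = mt),
                    class = "variant")
    expect_equal(as.numeric(variant_delta_fitness(transformed, wt_seq, vv)),
                 as.numeric(variant_delta_fitness(model, wt_seq, vv)),
                 tolerance = 1e-8)
  }
})

test_that("fitted models satisfy the zero-sum gauge conditions", {
  sim <- sample_potts_msa(m = 400, N = 3, q = 3, seed = 21)
  fit <- fit_potts_plm(sim$msa, weights = uniform_weights(400),
                       lambda_h = 0.01, lambda_J = 0.02, q = 3)
  expect_lt(max(abs(rowSums(fit$h))), 1e-6)
  for (i in 1:3) for (j in 1:3) if (i != j) {
    expect_lt(max(abs(colSums(fit$J[, , i, j]))), 1e-6)
    expect_lt(max(abs(rowSums(fit$J[, , i, j]))), 1e-6)
    expect_equal(fit$J[, , i, j], t(fit$J[, , j, i]))
  }
})

test_that("independent-site data yields weaker couplings than coupled data", {
  m <- 800
  null_sim <- sample_potts_msa(m = m, N = 3, q = 3, J_sd = 0, seed = 31)
  dep_sim <- sample_potts_msa(m = m, N = 3, q = 3, J_sd = 1, seed = 31)
  fit_null <- fit_potts_plm(null_sim$msa, weights = uniform_weights(m),
                            lambda_h = 0.01, lambda_J = 0.02, q = 3)
  fit_dep <- fit_potts_plm(dep_sim$msa, weights = uniform_weights(m),
                           lambda_h = 0.01, lambda_J = 0.02, q = 3)
  offdiag <- function(fit) c(fit$J[, , 1, 2], fit$J[, , 1, 3], fit$J[, , 2, 3])
  expect_lt(mean(abs(offdiag(fit_null))), mean(abs(offdiag(fit_dep))))
  # couplings shrink as the penalty grows, vanishing in the ridge limit
  fit_dep_strong <- fit_potts_plm(dep_sim$msa, weights = uniform_weights(m),
                                  lambda_h = 0.01, lambda_J = 10, q = 3)
  expect_lt(mean(abs(offdiag(fit_dep_strong))),
            mean(abs(offdiag(fit_dep))))
  fit_ridge <- fit_potts_plm(dep_sim$msa, weights = uniform_weights(m),
                             lambda_h = 1e5, lambda_J = 1e5, q = 3)
  expect_lt(max(abs(fit_ridge$h)), 1e-2)
  expect_lt(max(abs(fit_ridge$J)), 1e-2)
})

test_that("coupling recovery improves with sample size", {
  cors <- sapply(c(200, 1000, 5000), function(m) {
    sim <- sample_potts_msa(m = m, N = 3, q = 3, seed = 11)
    fit <- fit_potts_plm(sim$msa, weights = uniform_weights(m),
                         lambda_h = 0.01, lambda_J = 0.02, q = 3)
    flat <- function(M) c(M$J[, , 1, 2], M$J[, , 1, 3], M$J[, , 2, 3])
    cor(flat(sim$model), flat(fit))
  })
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.9)
})

test_that("inference is deterministic and models round-trip through JSON", {
  sim <- sample_potts_msa(m = 300, N = 3, q = 3, seed = 8)
  f1 <- fit_potts_plm(sim$msa, weights = uniform_weights(300),
                      lambda_h = 0.01, lambda_J = 0.02, q = 3)
  f2 <- fit_potts_plm(sim$msa, weights = uniform_weights(300),
                      lambda_h = 0.01, lambda_J = 0.02, q = 3)
  expect_identical(f1$h, f2$h)
  expect_identical(f1$J, f2$J)
  path <- withr::local_tempfile(fileext = ".json")
  write_potts_model(f1, path)
  back <- read_potts_model(path)
  expect_equal(back$h, f1$h, tolerance = 1e-12)
  expect_equal(back$J, f1$J, tolerance = 1e-12)
  expect_equal(back$alphabet, f1$alphabet)
})

test_that("gap positions in the wild type score zero with a flag", {
  sim <- sample_potts_msa(m = 5, N = 3, q = 3, seed = 6)
  model <- sim$model
  model$alphabet <- c("A", "C", "-")
  wt_seq <- c("A", "-", "C")
  v <- structure(list(position = 2L, wt = "C", mt = "A"), class = "variant")
  got <- variant_delta_fitness(model, wt_seq, v)
  expect_equal(as.numeric(got), 0)
  expect_true(attr(got, "gap_column"))
})
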