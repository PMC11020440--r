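test_that("intercept-only coefficients score every variant at 1", {
  alpha <- c(RSA = 0, PoP = 0, MAE = 0, SNP = 0, PVS = 0, CI = 0,
             LOR = 0, PYF = 0, `(Intercept)` = 1)
  fv <- random_features(50, seed = 1)
  expect_equal(linear_score(fv, alpha), rep(1, 50))
})

test_that("linear scores equal the dot-product oracle on random inputs", {
  for (s in 1:20) {
    fv <- random_features(10, seed = 400 + s)
    alpha <- random_alpha(seed = 500 + s)
    expected <- as.matrix(fv) %*% alpha[colnames(fv)] + alpha["(Intercept)"]
    expect_equal(linear_score(fv, alpha), drop(expected),
                 ignore_attr = TRUE)
  }
  # scoring is linear in the coefficients
  fv <- random_features(5, seed = 777)
  alpha <- random_alpha(seed = 778)
  s1 <- linear_score(fv, alpha)
  alpha2 <- alpha * 2
  expect_equal(linear_score(fv, alpha2), 2 * s1)
})

test_that("incomplete features are an error until imputation runs", {
  fv <- random_features(5, seed = 2)
  fv$PoP[3] <- NA
  alpha <- random_alpha(seed = 3)
  expect_error(linear_score(fv, alpha), "impute")
  expect_silent(linear_score(impute_missing(fv), alpha))
})

test_that("noiseless synthetic data is interpolated exactly", {
  train <- make_synthetic_dms(n = 500, noise_sd = 0, seed = 5)
  fit <- varfit(train)
  expect_equal(unname(fit$alpha), unname(attr(train, "true_alpha")),
               tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("rank-deficient designs error under ols and pass under ridge", {
  train <- make_synthetic_dms(n = 100, seed = 6)
  train$MAE <- train$PoP   # duplicated feature column
  expect_error(varfit(train, method = "ols"), "ridge")
  fit <- varfit(train, method = "ridge")
  expect_s3_class(fit, "varfit")
  expect_true(all(is.finite(fit$alpha)))
})

test_that("coefficient estimates are unbiased within sampling error", {
  truth <- default_true_alpha()$alpha
  hits <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    train <- make_synthetic_dms(n = 2000, noise_sd = 0.1, seed = 1000 + s)
    fit <- varfit(train)
    if (all(abs(fit$alpha - truth) <= 3 * fit$se)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("affine SNP rescaling matches its closed form", {
  expect_equal(rescaled_snp(c(-2, 0, 3), c(1, 0)), c(-2, 0, 3))
  expect_equal(rescaled_snp(c(-2, 0, 3), c(0, 0.7)), rep(0.7, 3))
  for (s in 1:10) {
    x <- withr::with_seed(600 + s, rnorm(20, sd = 3))
    b <- withr::with_seed(620 + s, rnorm(2))
    expect_equal(rescaled_snp(x, b), b[1] * x + b[2])
  }
})

test_that("double-ReLU rescaling equals the unit-interval clamp", {
  g <- c(1, 0)
  expect_equal(rescaled_pop(-5, g), 0)
  expect_equal(rescaled_pop(7, g), 1)
  expect_equal(rescaled_pop(0.42, g), 0.42)
  grid <- seq(-30, 30, by = 0.01)
  for (gam in list(c(0.8, 0.1), c(-1.2, 0.5), c(0.05, 0.99))) {
    lhs <- rescaled_pop(grid, gam)
    rhs <- pmin(pmax(gam[1] * grid + gam[2], 0), 1)
    expect_lt(max(abs(lhs - rhs)), 1e-12)
    expect_true(all(lhs >= 0 & lhs <= 1))
  }
})

test_that("structural/evolutionary decomposition sums back to the score", {
  alpha <- random_alpha(seed = 9)
  fv <- random_features(100, seed = 10)
  parts <- decompose_score(fv, alpha)
  total <- parts$STR + parts$EVO + alpha["RSA"] * fv$RSA +
    alpha["(Intercept)"]
  expect_equal(total, linear_score(fv, alpha), tolerance = 1e-10,
               ignore_attr = TRUE)
  # zero structural features force STR = 0
  fv0 <- fv
  fv0$PoP <- 0; fv0$MAE <- 0; fv0$SNP <- 0
  expect_equal(decompose_score(fv0, alpha)$STR, rep(0, 100))
})

test_that("z-scores standardize exactly and ignore affine shifts", {
  tab <- data.frame(score = c(0.1, 0.4, 0.9, 1.2, 0.6),
                    STR = c(-1, 0, 1, 2, 0.5),
                    EVO = c(2, 1, 0, -1, 0.5))
  z <- zscores(tab)
  for (col in c("Z", "Z_str", "Z_evo")) {
    expect_lt(abs(mean(z[[col]])), 1e-9)
    expect_lt(abs(sqrt(mean((z[[col]] - mean(z[[col]]))^2)) - 1), 1e-9)
  }
  # hand oracle for the first column
  mu <- mean(tab$score)
  sg <- sqrt(mean((tab$score - mu)^2))
  expect_equal(z$Z, (tab$score - mu) / sg)
  # z-scores are invariant to affine transforms of the raw values
  tab2 <- tab
  tab2$score <- 3 * tab$score + 7
  expect_equal(zscores(tab2)$Z, z$Z, tolerance = 1e-12)
  # constant scores cannot be standardized
  tab3 <- tab
  tab3$STR <- 1
  expect_error(zscores(tab3), "constant")
})

test_that("standardizing over a partial landscape warns", {
  tab <- data.frame(position = rep(1:2, each = 3),
                    score = rnorm(6), STR = rnorm(6), EVO = rnorm(6))
  expect_warning(zscores(tab), "subset")
})

test_that("per-residue summaries equal a group-by oracle", {
  tab <- data.frame(position = rep(1:4, each = 19))
  tab$score <- withr::with_seed(11, rnorm(nrow(tab)))
  tab$STR <- withr::with_seed(12, rnorm(nrow(tab)))
  tab$EVO <- withr::with_seed(13, rnorm(nrow(tab)))
  z <- zscores(tab)
  prs <- per_residue_summary(z)
  for (p in 1:4) {
    expect_equal(prs$Z_evo[prs$position == p],
                 mean(z$Z_evo[z$position == p]))
    expect_equal(prs$Z_str[prs$position == p],
                 mean(z$Z_str[z$position == p]))
  }
  # constant z-scores average to the constant
  zc <- z
  zc$Z <- zc$Z_str <- zc$Z_evo <- 0.25
  expect_equal(per_residue_summary(zc)$Z, rep(0.25, 4))
  expect_equal(subset_mean_zscore(z$Z, z$score > 0),
               mean(z$Z[z$score > 0]))
  expect_error(subset_mean_zscore(z$Z, rep(FALSE, nrow(z))), "empty")
})

test_that("coefficients round-trip through the JSON container", {
  alpha <- random_alpha(seed = 21)
  co <- varfit_coefficients(alpha, beta = c(1.1, -0.3),
                            gamma = c(0.9, 0.05),
                            provenance = "unit test")
  f <- withr::local_tempfile(fileext = ".json")
  write_coefficients(co, f)
  back <- read_coefficients(f)
  expect_equal(back$alpha, co$alpha, tolerance = 1e-12)
  expect_equal(back$beta, co$beta)
  expect_equal(back$gamma, co$gamma)
  expect_equal(back$provenance, "unit test")
})

test_that("model methods behave like standard fitted-model accessors", {
  train <- make_synthetic_dms(n = 300, seed = 30)
  fit <- varfit(train)
  expect_named(coef(fit), c("RSA", "PoP", "MAE", "SNP", "PVS", "CI",
                            "LOR", "PYF", "(Intercept)"))
  expect_equal(fitted(fit) + residuals(fit), train$fitness)
  expect_equal(predict(fit, train), fitted(fit))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.varfit")
  expect_gt(sm$evo_str_ratio, 1)
  sims <- simulate(fit, nsim = 3, seed = 4)
  expect_equal(dim(sims), c(300L, 3L))
  expect_identical(simulate(fit, nsim = 3, seed = 4), sims)
  expect_output(print(fit), "evolutionary/structural")
})
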