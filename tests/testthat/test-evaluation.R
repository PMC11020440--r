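test_that("hyper-complementing filter removes strictly-above values only", {
  set <- data.frame(exp = c(0.5, 1.36, 1.40))
  out <- filter_hypercomplementing(set)
  expect_equal(out$exp, c(0.5, 1.36))
  expect_match(attr(out, "filter_log"), "removed 1 of 3")
  # infinite cutoff is the identity
  out2 <- filter_hypercomplementing(set, cutoff = Inf)
  expect_equal(out2$exp, set$exp)
  # everything above the cutoff leaves an empty set with a warning
  expect_warning(out3 <- filter_hypercomplementing(data.frame(exp = c(2, 3))),
                 "all variants removed")
  expect_equal(nrow(out3), 0L)
  # idempotence
  expect_equal(filter_hypercomplementing(out)$exp, out$exp)
})

test_that("floor/SE filter floors negatives and excludes strictly above 0.3", {
  set <- data.frame(exp = c(-0.2, 0.5, 0.9, 1.0),
                    se = c(0.1, 0.3, 0.31, NA))
  out <- filter_floor_and_se(set)
  expect_equal(out$exp, c(0.0, 0.5, 1.0))   # SE 0.3 kept, 0.31 removed
  expect_equal(filter_floor_and_se(out)$exp, out$exp)  # idempotent
  # without an SE column, flooring still happens
  expect_warning(out2 <- filter_floor_and_se(data.frame(exp = c(-1, 0.5))),
                 "skipped")
  expect_equal(out2$exp, c(0, 0.5))
})

test_that("correlation metrics: identity, monotone transforms, and ties", {
  x <- c(0.2, 0.5, 0.9, 1.1, 0.4, 0.7)
  m <- correlation_metrics(x, x)
  expect_equal(unlist(m[c("kendall", "spearman", "pearson", "rmsd")]),
               c(kendall = 1, spearman = 1, pearson = 1, rmsd = 0))
  dec <- correlation_metrics(-x^3, x)
  expect_equal(dec$kendall, -1)
  expect_equal(dec$spearman, -1)
  expect_error(correlation_metrics(rep(1, 6), x), "constant")
  expect_error(correlation_metrics(x[1:2], x[1:2]), "at least 3")
})

test_that("tied data reproduce exhaustive pair-counting oracles", {
  pred <- c(1, 2, 2, 3, 4, 4)
  ex <- c(2, 1, 3, 3, 5, 4)
  m <- correlation_metrics(pred, ex)
  # tau-b by explicit pair enumeration
  n <- length(pred); C <- 0; D <- 0; Tx <- 0; Ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(pred[j] - pred[i]); dy <- sign(ex[j] - ex[i])
    if (dx * dy > 0) C <- C + 1 else if (dx * dy < 0) D <- D + 1
    if (dx == 0 && dy != 0) Tx <- Tx + 1
    if (dy == 0 && dx != 0) Ty <- Ty + 1
  }
  expect_equal(m$kendall, (C - D) / sqrt((C + D + Tx) * (C + D + Ty)))
  # spearman as pearson of mid-ranks
  expect_equal(m$spearman, cor(rank(pred), rank(ex)))
  # explicit pearson and rmsd formulas
  expect_equal(m$pearson,
               sum((pred - mean(pred)) * (ex - mean(ex))) /
                 sqrt(sum((pred - mean(pred))^2) * sum((ex - mean(ex))^2)))
  expect_equal(m$rmsd, sqrt(mean((pred - ex)^2)))
})

test_that("rank correlations are invariant under monotone transforms", {
  for (s in 1:10) {
    x <- withr::with_seed(700 + s, rnorm(25))
    y <- withr::with_seed(720 + s, rnorm(25))
    m0 <- correlation_metrics(x, y)
    m1 <- correlation_metrics(exp(x), y)       # strictly increasing
    expect_equal(m1$spearman, m0$spearman, tolerance = 1e-12)
    expect_equal(m1$kendall, m0$kendall, tolerance = 1e-12)
    m2 <- correlation_metrics(2.5 * x + 1, y)  # positive affine
    expect_equal(m2$pearson, m0$pearson, tolerance = 1e-12)
  }
})

test_that("classification metrics follow the low-fitness-is-pathogenic rule", {
  pred <- c(0.1, 0.2, 0.3, 0.8, 0.9, 1.0)
  lab <- c(rep("pathogenic", 3), rep("benign", 3))
  m <- classification_metrics(pred, lab, threshold = 0.5)
  expect_equal(unlist(m[c("sensitivity", "specificity", "bacc")]),
               c(sensitivity = 1, specificity = 1, bacc = 1))
  # threshold below every score: nothing called pathogenic
  m2 <- classification_metrics(pred, lab, threshold = 0)
  expect_equal(unlist(m2[c("sensitivity", "specificity", "bacc")]),
               c(sensitivity = 0, specificity = 1, bacc = 0.5))
  expect_error(classification_metrics(pred, rep("benign", 6)), "non-empty")
})

test_that("a 10-variant table matches the confusion-matrix oracle", {
  pred <- c(0.2, 0.6, 0.4, 0.45, 0.7, 0.9, 0.3, 0.55, 0.1, 0.65)
  lab <- c("pathogenic", "pathogenic", "pathogenic", "benign", "benign",
           "benign", "pathogenic", "benign", "pathogenic", "benign")
  thr <- 0.5
  tp <- sum(pred < thr & lab == "pathogenic")
  fn <- sum(pred >= thr & lab == "pathogenic")
  tn <- sum(pred >= thr & lab == "benign")
  fp <- sum(pred < thr & lab == "benign")
  m <- classification_metrics(pred, lab, thr)
  expect_equal(m$sensitivity, tp / (tp + fn))
  expect_equal(m$specificity, tn / (tn + fp))
  expect_equal(m$bacc, (m$sensitivity + m$specificity) / 2)
})

test_that("AUC: perfect separation, null behaviour, and double oracle", {
  pred <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  lab <- c("pathogenic", "pathogenic", "pathogenic", "benign", "benign")
  expect_equal(auc_roc(pred, lab), 1)
  # labels independent of scores: AUC near 1/2
  big_pred <- withr::with_seed(42, runif(4000))
  big_lab <- withr::with_seed(43, sample(c("pathogenic", "benign"), 4000,
                                         replace = TRUE))
  expect_lt(abs(auc_roc(big_pred, big_lab) - 0.5), 0.05)
  # rank formulation equals trapezoidal ROC integration
  for (s in 1:20) {
    n <- withr::with_seed(800 + s, sample(8:50, 1))
    p <- withr::with_seed(820 + s, round(runif(n), 2))  # forces ties
    l <- withr::with_seed(840 + s,
                          sample(c("pathogenic", "benign"), n,
                                 replace = TRUE))
    if (length(unique(l)) < 2) l[1:2] <- c("pathogenic", "benign")
    got <- auc_roc(p, l)
    # trapezoidal ROC over all distinct thresholds of the oriented score
    x <- -p
    ths <- c(-Inf, sort(unique(x)), Inf)
    tpr <- sapply(ths, function(t) mean(x[l == "pathogenic"] >= t))
    fpr <- sapply(ths, function(t) mean(x[l == "benign"] >= t))
    ord <- order(fpr, tpr)
    trap <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                                    utils::tail(tpr[ord], -1)) / 2)
    expect_equal(got, trap, tolerance = 1e-10)
  }
})

test_that("the evaluation wrapper applies filters and polarity", {
  set <- data.frame(pred = c(0.1, 0.5, 0.8, 0.9, 1.2, 0.4),
                    exp = c(0.0, 0.6, 0.9, 1.0, 1.5, 0.3),
                    label = c("pathogenic", NA, "benign", "benign", NA,
                              "pathogenic"))
  rep <- evaluate_predictions(set)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n, 5L)   # the exp = 1.5 row is filtered out
  expect_length(rep$filter_log, 1L)
  expect_true(is.finite(rep$auc_roc))
  # flipped-polarity predictors evaluate identically after negation
  set2 <- set
  set2$pred <- -set2$pred
  rep2 <- evaluate_predictions(set2, polarity = -1)
  expect_equal(rep2$spearman, rep$spearman)
  expect_equal(rep2$auc_roc, rep$auc_roc)
})
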