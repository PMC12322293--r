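test_that("stratified splits preserve class proportions and determinism", {
  ph <- random_pheno(sprintf("s%02d", 1:20), n_r = 10, seed = 1)
  sp <- stratified_split(ph, 0.2, seed = 5)
  test_lab <- ph$label[match(sp$test_ids, ph$sample_id)]
  expect_equal(sum(test_lab == "R"), 2)
  expect_equal(sum(test_lab == "NR"), 2)
  expect_setequal(c(sp$train_ids, sp$test_ids), ph$sample_id)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_identical(stratified_split(ph, 0.2, seed = 5), sp)
  expect_false(identical(stratified_split(ph, 0.2, seed = 6)$test_ids, sp$test_ids))
})

test_that("unbalanced splits stay within one sample of the exact fraction", {
  ph <- random_pheno(sprintf("s%02d", 1:20), n_r = 7, seed = 2)  # 7 R, 13 NR
  for (seed in 1:10) {
    sp <- stratified_split(ph, 0.2, seed = seed)
    test_lab <- ph$label[match(sp$test_ids, ph$sample_id)]
    expect_lte(abs(sum(test_lab == "R") - 7 * 0.2), 1)
    expect_lte(abs(sum(test_lab == "NR") - 13 * 0.2), 1)
  }
  ph_small <- phenotype_table(setNames(c("R", "NR", "NR"), paste0("s", 1:3)))
  expect_error(stratified_split(ph_small, 0.2, 1), "at least 2")
})

test_that("ridge logistic behaves like a regularized monotone classifier", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic_l2(x, y, lambda = 0.01)
  pr <- predict(fit, x)
  expect_true(all(diff(pr) > 0))
  expect_equal(rank_auc(pr, y), 1)

  # sign symmetry
  fit_neg <- fit_logistic_l2(-x, y, lambda = 0.01)
  expect_equal(coef(fit_neg)[2], -coef(fit)[2], tolerance = 1e-6,
               ignore_attr = TRUE)

  # penalty -> infinity: slopes vanish, probabilities -> class prior
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y2 <- rep(c(0, 1), 10)
  fit_inf <- fit_logistic_l2(X, y2, lambda = 1e8)
  expect_lt(max(abs(coef(fit_inf)[-1])), 1e-5)
  expect_equal(unname(predict(fit_inf, X)), rep(0.5, 20), tolerance = 1e-3)

  # constant features: fit succeeds, probabilities equal the prior
  Xc <- matrix(1, 12, 2)
  y3 <- rep(c(1, 0), c(4, 8))
  fitc <- fit_logistic_l2(Xc, y3, lambda = 1)
  expect_equal(unname(predict(fitc, Xc)), rep(1 / 3, 12), tolerance = 0.05)
})

test_that("ridge logistic agrees with glmnet on a multi-feature fixture", {
  skip_if_not_installed("glmnet")
  set.seed(9)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(0.5 + X %*% c(1, -0.5, 0.2)))
  lambda <- 0.7
  ours <- fit_logistic_l2(X, y, lambda = lambda)
  # glmnet minimizes (1/n) * nll + lambda_g * ||b||^2 / 2 on standardized = FALSE
  gn <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = lambda / n, standardize = FALSE,
                       thresh = 1e-12)
  expect_equal(unname(coef(ours)),
               unname(as.numeric(coef(gn))), tolerance = 1e-3)
})

test_that("cross-validated family comparison honors its contract", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60, mean = 3), 30, 2),
             matrix(rnorm(60, mean = -3), 30, 2))
  y <- rep(c("R", "NR"), each = 30)
  res <- crossval_model_selection(X, y, k = 10, seed = 2)
  expect_equal(nrow(res$cv_table), 5)
  expect_setequal(res$cv_table$model,
                  c("logistic", "svm", "knn", "perceptron", "tree"))
  expect_true(all(res$cv_table$mean_accuracy >= 0 &
                    res$cv_table$mean_accuracy <= 1))
  # wide margin: every family separates, tie-break picks logistic
  expect_true(all(res$cv_table$mean_accuracy == 1))
  expect_identical(res$best_model, "logistic")
  expect_error(crossval_model_selection(X[1:5, ], y[1:5], k = 10), "smaller k")
})

test_that("permuted labels give chance-level CV accuracy for every family", {
  set.seed(21)
  X <- matrix(rnorm(80), 40, 2)
  acc <- replicate(20, {
    y <- sample(rep(c(1, 0), c(16, 24)))
    crossval_model_selection(X, y, k = 5, seed = 1)$cv_table$mean_accuracy
  })
  # majority-class rate is 0.6; binomial noise at n = 40 over 20 permutations
  expect_true(all(abs(rowMeans(acc) - 0.6) < 0.12))
})

test_that("metrics match hand counts and the pair-enumeration AUC oracle", {
  m <- evaluate_classifier(c(0.9, 0.8, 0.1, 0.2), y_test = c("R", "R", "NR", "NR"))
  expect_equal(unlist(m), c(precision = 1, recall = 1, accuracy = 1, auc = 1))

  tied <- evaluate_classifier(rep(0.5, 6), y_test = c("R", "R", "R", "NR", "NR", "NR"))
  expect_equal(tied$auc, 0.5)

  set.seed(6)
  probs <- c(0.7, 0.3, 0.55, 0.55, 0.2, 0.9)
  y <- c(1, 0, 1, 0, 1, 0)
  ours <- evaluate_classifier(probs, y_test = y)
  expect_equal(ours$auc, oracle_auc(probs, y), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(ours$auc,
               as.numeric(pROC::auc(pROC::roc(y, probs, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("degenerate test sets are reported, not crashed on", {
  expect_warning(m <- evaluate_classifier(c(0.9, 0.8), y_test = c("R", "R")),
                 "single class")
  expect_true(is.na(m$auc))
  expect_equal(m$recall, 1)
  # no positive predictions: precision undefined
  m2 <- evaluate_classifier(c(0.1, 0.2, 0.3), y_test = c("NR", "NR", "R"))
  expect_true(is.na(m2$precision))
  expect_equal(m2$recall, 0)
})

test_that("rank AUC equals trapezoidal ROC integration", {
  set.seed(31)
  for (i in 1:5) {
    scores <- round(runif(30), 2)   # rounding forces ties
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    # trapezoidal integration over the empirical ROC curve
    th <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
    tpr <- sapply(th, function(t) mean(scores[y == 1] >= t))
    fpr <- sapply(th, function(t) mean(scores[y == 0] >= t))
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(rank_auc(scores, y), trap, tolerance = 1e-12)
  }
})
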