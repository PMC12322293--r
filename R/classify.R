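#' Stratified train/test split
#'
#' Samples a test set of roughly `test_fraction` of the cohort with class
#' proportions preserved: per class, `round(n_class * test_fraction)` samples
#' (at least 1) go to the test set. Deterministic under `seed`.
#'
#' @param pheno a [phenotype_table()].
#' @param test_fraction fraction held out (default 0.2, the 4:1 split).
#' @param seed integer seed.
#' @return List with `train_ids`, `test_ids`, `seed`.
#' @export
stratified_split <- function(pheno, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  counts <- table(pheno$label)
  if (any(counts < 2))
    mf_stop("each class needs at least 2 samples to split (got ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")")
  set.seed(as.integer(seed))
  test_ids <- character(0)
  for (cl in sort(names(counts))) {
    ids <- pheno$sample_id[pheno$label == cl]
    n_test <- max(1L, as.integer(round(length(ids) * test_fraction)))
    if (n_test >= length(ids)) mf_stop("test fraction leaves no training samples for class ", cl)
    test_ids <- c(test_ids, sample(ids, n_test))
  }
  list(train_ids = setdiff(pheno$sample_id, test_ids),
       test_ids = test_ids, seed = as.integer(seed))
}

#' @keywords internal
#' @noRd
stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' L2-regularized logistic regression
#'
#' Ridge-penalized logistic fit by iteratively reweighted least squares:
#' minimizes the negative log-likelihood plus `lambda / 2 * sum(beta^2)` over
#' the slope coefficients (the intercept is unpenalized). Works for any
#' number of features, including a single column, and remains well-defined
#' under complete separation or constant features (where probabilities
#' collapse to the class prior).
#'
#' @param X numeric feature matrix (samples x features).
#' @param y labels: factor/character with levels R/NR, or 0/1 numeric
#'   (R = 1 is the positive class).
#' @param lambda ridge penalty (default 1).
#' @param max_iter,tol IRLS controls.
#' @return An object of class `mf_logistic` with elements `coefficients`
#'   (intercept first), `lambda`, `converged`.
#' @export
fit_logistic_l2 <- function(X, y, lambda = 1, max_iter = 100, tol = 1e-9) {
  X <- as.matrix(X)
  y01 <- encode_labels(y)
  if (length(unique(y01)) < 2) mf_stop("both classes must be present to fit")
  n <- nrow(X); p <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  beta <- rep(0, p + 1)
  obj <- function(b) {
    eta <- drop(Xd %*% b)
    sum(log1p(exp(-(2 * y01 - 1) * eta))) + sum(lambda / 2 * b[-1]^2)
  }
  f_old <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xd, y01 - mu)) - c(0, lambda * beta[-1])
    hess <- crossprod(Xd * w, Xd) + pen
    step <- solve(hess, grad)
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * step
      f_new <- obj(beta_new)
      if (f_new <= f_old + 1e-12 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    beta <- beta_new
    if (abs(f_old - f_new) < tol * (abs(f_old) + tol)) { converged <- TRUE; break }
    f_old <- f_new
  }
  structure(list(coefficients = stats::setNames(beta, colnames(Xd)),
                 lambda = lambda, converged = converged,
                 feature_names = colnames(X) %||% paste0("V", seq_len(p))),
            class = "mf_logistic")
}

#' @export
coef.mf_logistic <- function(object, ...) object$coefficients

#' @rdname fit_logistic_l2
#' @param object fitted `mf_logistic` model.
#' @param newdata feature matrix for prediction.
#' @param type `"prob"` for P(R) or `"class"` for thresholded labels.
#' @param threshold classification threshold for `type = "class"`.
#' @param ... unused.
#' @export
predict.mf_logistic <- function(object, newdata, type = c("prob", "class"),
                                threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  eta <- drop(cbind(1, X) %*% object$coefficients)
  pr <- stats::plogis(eta)
  if (type == "prob") pr else ifelse(pr > threshold, "R", "NR")
}

#' @keywords internal
#' @noRd
encode_labels <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) mf_stop("numeric labels must be 0/1")
    return(as.numeric(y))
  }
  y <- as.character(y)
  bad <- setdiff(unique(y), c("R", "NR"))
  if (length(bad)) mf_stop("labels must be R/NR, found: ", paste(bad, collapse = ", "))
  as.numeric(y == "R")
}

# Rosenblatt perceptron: deterministic epoch order, standardized features.
#' @keywords internal
#' @noRd
fit_perceptron <- function(X, y01, epochs = 100, rate = 1) {
  mu <- colMeans(X); sdev <- apply(X, 2, stats::sd); sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  w <- rep(0, ncol(X)); b <- 0
  t <- 2 * y01 - 1
  for (e in seq_len(epochs)) {
    updated <- FALSE
    for (i in seq_len(nrow(Xs))) {
      if (t[i] * (sum(w * Xs[i, ]) + b) <= 0) {
        w <- w + rate * t[i] * Xs[i, ]
        b <- b + rate * t[i]
        updated <- TRUE
      }
    }
    if (!updated) break
  }
  list(w = w, b = b, mu = mu, sd = sdev)
}

#' @keywords internal
#' @noRd
predict_perceptron <- function(model, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, model$mu), 2, model$sd, "/")
  as.numeric(drop(Xs %*% model$w) + model$b > 0)
}

#' Cross-validated model family selection
#'
#' Stratified k-fold cross-validation of five classifier families at fixed
#' default hyperparameters: L2 logistic regression, RBF support vector
#' machine, k-nearest neighbors (k = 5), perceptron, and a decision tree.
#' The best family is the one with the highest mean fold accuracy; ties are
#' broken by the fixed priority logistic > svm > knn > perceptron > tree.
#'
#' @param X feature matrix (samples x features).
#' @param y R/NR labels (or 0/1).
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param lambda ridge penalty for the logistic family.
#' @return List with `cv_table` (data frame: model, mean_accuracy) and
#'   `best_model` (family name).
#' @export
crossval_model_selection <- function(X, y, k = 10, seed = 1L, lambda = 1) {
  X <- as.matrix(X)
  y01 <- encode_labels(y)
  n <- nrow(X)
  if (k > n) mf_stop("k (", k, ") exceeds the sample count (", n, "); use a smaller k")
  if (length(unique(y01)) < 2) mf_stop("both classes required")
  fold <- stratified_folds(y01, k, seed)
  families <- c("logistic", "svm", "knn", "perceptron", "tree")
  acc <- matrix(NA_real_, k, length(families), dimnames = list(NULL, families))
  yfac <- factor(ifelse(y01 == 1, "R", "NR"), levels = c("NR", "R"))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y01[tr])) < 2 || !any(te)) next
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    hit <- function(pred01) mean(pred01 == y01[te])
    fit <- fit_logistic_l2(Xtr, y01[tr], lambda = lambda)
    acc[f, "logistic"] <- hit(as.numeric(predict(fit, Xte) > 0.5))
    sv <- e1071::svm(Xtr, yfac[tr], kernel = "radial")
    acc[f, "svm"] <- hit(as.numeric(predict(sv, Xte) == "R"))
    kk <- min(5L, nrow(Xtr))
    acc[f, "knn"] <- hit(as.numeric(class::knn(Xtr, Xte, yfac[tr], k = kk) == "R"))
    pc <- fit_perceptron(Xtr, y01[tr])
    acc[f, "perceptron"] <- hit(predict_perceptron(pc, Xte))
    df_tr <- data.frame(y = yfac[tr], Xtr, check.names = FALSE)
    df_te <- data.frame(Xte, check.names = FALSE)
    tree <- rpart::rpart(y ~ ., data = df_tr, method = "class",
                         control = rpart::rpart.control(minsplit = 5, cp = 0.01))
    acc[f, "tree"] <- hit(as.numeric(predict(tree, df_te, type = "class") == "R"))
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  cv_table <- data.frame(model = families, mean_accuracy = unname(mean_acc),
                         stringsAsFactors = FALSE)
  best <- families[which.max(mean_acc)]  # which.max takes the first maximum,
  # and `families` is already ordered by the tie-break priority
  list(cv_table = cv_table, best_model = best)
}

#' Rank-based AUC
#'
#' Mann-Whitney formulation: the probability that a random R sample scores
#' above a random NR sample, with ties contributing 1/2.
#' @param scores numeric scores (higher = more R-like).
#' @param y R/NR labels (or 0/1).
#' @return AUC in \[0, 1\]; NA with a warning if only one class is present.
#' @export
rank_auc <- function(scores, y) {
  y01 <- encode_labels(y)
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Test-set metrics for a fitted classifier
#'
#' Precision, recall, accuracy (labels thresholded at `threshold`, R as the
#' positive class) and rank-based AUC from the continuous scores.
#'
#' @param model an `mf_logistic` fit, or a numeric vector of P(R) scores of
#'   length `nrow(X_test)` (in which case `X_test` may be NULL).
#' @param X_test test feature matrix.
#' @param y_test test labels.
#' @param threshold classification threshold (default 0.5).
#' @return One-row data frame: `precision`, `recall`, `accuracy`, `auc`.
#'   Precision is NA when no sample is predicted positive; AUC is NA for a
#'   single-class test set (with a warning; the other metrics are still
#'   computed).
#' @export
evaluate_classifier <- function(model, X_test = NULL, y_test, threshold = 0.5) {
  probs <- if (is.numeric(model)) model else predict(model, X_test, type = "prob")
  y01 <- encode_labels(y_test)
  if (length(probs) != length(y01)) mf_stop("scores and labels differ in length")
  pred <- as.numeric(probs > threshold)
  tp <- sum(pred == 1 & y01 == 1); fp <- sum(pred == 1 & y01 == 0)
  fn <- sum(pred == 0 & y01 == 1)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  auc <- if (length(unique(y01)) < 2) {
    warning("AUC undefined: test set has a single class", call. = FALSE)
    NA_real_
  } else rank_auc(probs, y01)
  data.frame(precision = precision, recall = recall,
             accuracy = mean(pred == y01), auc = auc)
}
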