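#' Pipeline configuration for repeated evaluation
#'
#' @param mode `"strict"` refits the whole chain (filtering, network, GS,
#'   gene selection, MF normalization, classifier) on each training split;
#'   `"paper"` fits network/GS/selection/normalization once on the full
#'   cohort and lets only the classifier respect the split — the common
#'   published practice, kept so the train-to-test information leak it
#'   introduces can be measured against strict mode.
#' @param n_repeats number of random stratified splits (default 50).
#' @param test_fraction held-out fraction (default 0.2, the 4:1 split).
#' @param seed0 base seed; repeat r uses `seed0 + r`.
#' @param gs_min,fdr_max,min_total,min_fraction,lambda,feature_selection,cv_select,cv_k
#'   forwarded to [mf_fit()].
#' @param threshold classification threshold for precision/recall/accuracy.
#' @param params a [network_params()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("strict", "paper"), n_repeats = 50,
                            test_fraction = 0.2, seed0 = 1L,
                            gs_min = 0.1, fdr_max = 0.4,
                            min_total = 50, min_fraction = 0.02,
                            lambda = 1, feature_selection = "all",
                            cv_select = TRUE, cv_k = 10, threshold = 0.5,
                            params = network_params()) {
  mode <- match.arg(mode)
  stopifnot(n_repeats >= 1, test_fraction > 0, test_fraction < 1)
  structure(list(mode = mode, n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, seed0 = as.integer(seed0),
                 gs_min = gs_min, fdr_max = fdr_max, min_total = min_total,
                 min_fraction = min_fraction, lambda = lambda,
                 feature_selection = feature_selection, cv_select = cv_select,
                 cv_k = cv_k, threshold = threshold, params = params),
            class = "pipeline_config")
}

#' Repeated stratified-split evaluation
#'
#' The evaluation protocol: the cohort is split 4:1 by stratified random
#' sampling `n_repeats` times; per repeat a model is trained and the
#' held-out samples are scored; precision, recall, accuracy and AUC are
#' collected per repeat and summarized by their medians.
#'
#' In strict mode every repeat refits the entire chain on its training
#' split. In paper mode the network, gene statistics, gene selection and
#' min-max normalization are fitted once on all samples and only the final
#' classifier is refitted per split; the difference between the two modes
#' on a trait-null cohort measures the information leak of pre-split
#' network fitting.
#'
#' A repeat whose model fit fails (e.g. no gene survives selection on that
#' training split) is recorded as failed; more than 20% failed repeats
#' aborts with an error.
#'
#' @param expr raw-scale [expression_matrix()].
#' @param pheno a [phenotype_table()].
#' @param config a [pipeline_config()].
#' @return An `mf_report`: list with `per_repeat` (data frame), `medians`,
#'   `pooled_auc` (AUC over all repeats' test scores pooled), `config`,
#'   `failed` (character reasons, named by repeat).
#' @export
run_repeated_pipeline <- function(expr, pheno, config = pipeline_config()) {
  pheno <- align_phenotype(pheno, colnames(expr))
  full_fit <- NULL
  if (config$mode == "paper") {
    full_fit <- with(config, mf_fit(
      expr, pheno, params = params, gs_min = gs_min, fdr_max = fdr_max,
      min_total = min_total, min_fraction = min_fraction, lambda = lambda,
      feature_selection = feature_selection, cv_select = FALSE, seed = seed0))
  }
  rows <- vector("list", config$n_repeats)
  failed <- character(0)
  pooled_scores <- pooled_labels <- list()
  for (r in seq_len(config$n_repeats)) {
    seed_r <- derive_seed(config$seed0, r)
    res <- tryCatch(
      run_one_repeat(expr, pheno, config, full_fit, seed_r),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failed[as.character(r)] <- res
      rows[[r]] <- data.frame(repeat_index = r, precision = NA_real_,
                              recall = NA_real_, accuracy = NA_real_,
                              auc = NA_real_, best_model = NA_character_,
                              n_features = NA_integer_)
    } else {
      rows[[r]] <- data.frame(repeat_index = r, res$metrics,
                              best_model = res$best_model %||% NA_character_,
                              n_features = res$n_features)
      pooled_scores[[r]] <- res$scores
      pooled_labels[[r]] <- res$labels
    }
  }
  if (length(failed) > 0.2 * config$n_repeats)
    mf_stop("more than 20% of repeats failed; first failure: ", failed[1])
  per_repeat <- do.call(rbind, rows)
  metric_cols <- c("precision", "recall", "accuracy", "auc")
  medians <- vapply(per_repeat[metric_cols],
                    function(z) stats::median(z, na.rm = TRUE), numeric(1))
  pooled_auc <- if (length(pooled_scores))
    rank_auc(unlist(pooled_scores), unlist(pooled_labels)) else NA_real_
  structure(list(per_repeat = per_repeat, medians = medians,
                 pooled_auc = pooled_auc, failed = failed, config = config),
            class = "mf_report")
}

#' @keywords internal
#' @noRd
run_one_repeat <- function(expr, pheno, config, full_fit, seed_r) {
  split <- stratified_split(pheno, config$test_fraction, seed = seed_r)
  test_pheno <- pheno[match(split$test_ids, pheno$sample_id), , drop = FALSE]
  if (config$mode == "strict") {
    train_pheno <- pheno[match(split$train_ids, pheno$sample_id), , drop = FALSE]
    fit <- with(config, mf_fit(
      expr[, split$train_ids], train_pheno, params = params,
      gs_min = gs_min, fdr_max = fdr_max, min_total = min_total,
      min_fraction = min_fraction, lambda = lambda,
      feature_selection = feature_selection, cv_select = cv_select,
      cv_k = cv_k, seed = seed_r))
    scores <- predict(fit, expr[, split$test_ids])
    best <- fit$cv$best_model
    n_feat <- length(fit$selected_modules)
  } else {
    X <- full_fit$mf$values[, full_fit$selected_modules, drop = FALSE]
    y01 <- full_fit$pheno$trait
    tr <- rownames(X) %in% split$train_ids
    cv <- if (config$cv_select && sum(tr) >= config$cv_k)
      crossval_model_selection(X[tr, , drop = FALSE], y01[tr],
                               k = config$cv_k, seed = seed_r,
                               lambda = config$lambda) else NULL
    clf <- fit_logistic_l2(X[tr, , drop = FALSE], y01[tr], lambda = config$lambda)
    scores <- predict(clf, X[split$test_ids, , drop = FALSE])
    names(scores) <- split$test_ids
    best <- cv$best_model
    n_feat <- ncol(X)
  }
  metrics <- evaluate_classifier(unname(scores[split$test_ids]),
                                 y_test = test_pheno$label,
                                 threshold = config$threshold)
  list(metrics = metrics, scores = unname(scores[split$test_ids]),
       labels = test_pheno$trait, best_model = best, n_features = n_feat)
}

#' @export
print.mf_report <- function(x, ...) {
  ok <- sum(!is.na(x$per_repeat$auc))
  cat(sprintf("mf_report: %d repeats (%s mode), %d evaluated, %d failed\n",
              x$config$n_repeats, x$config$mode, ok, length(x$failed)))
  cat("median metrics:\n")
  print(round(x$medians, 3))
  cat(sprintf("pooled AUC: %.3f\n", x$pooled_auc))
  invisible(x)
}

#' Metric panel for an evaluation report
#'
#' Boxplots of per-repeat precision, recall, accuracy and AUC.
#' @param x an `mf_report`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.mf_report <- function(x, ...) {
  m <- x$per_repeat[, c("precision", "recall", "accuracy", "auc")]
  graphics::boxplot(m, ylim = c(0, 1), ylab = "metric value", ...)
  invisible(x)
}
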