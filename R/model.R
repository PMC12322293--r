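#' Fit the module-factor rejection risk model
#'
#' The full modelling chain on one cohort: low-signal gene filtering and
#' log-normalization (raw input only), soft-threshold selection at the
#' scale-free fit target, unsigned adjacency and topological overlap,
#' module detection, module- and gene-trait statistics, direction-aligned
#' gene selection (GS/FDR thresholds), module factor computation with
#' min-max normalization fitted on the training samples, optional forward
#' feature selection, 10-fold cross-validated comparison of five classifier
#' families, and a final L2-regularized logistic model on the selected
#' module factors.
#'
#' Everything is estimated from the samples given here, so fitting on a
#' training split and calling [predict.mf_model()] on held-out samples gives
#' a leakage-free evaluation.
#'
#' @param expr an [expression_matrix()]; raw-scale input is filtered and
#'   log-normalized, lognorm input is used as-is.
#' @param pheno a [phenotype_table()] covering the samples.
#' @param params a [network_params()].
#' @param gs_min,fdr_max gene selection thresholds (defaults 0.1 and 0.4).
#' @param min_total,min_fraction gene filter thresholds (see
#'   [filter_genes()]).
#' @param lambda ridge penalty of the final logistic model.
#' @param feature_selection `"all"` keeps every module surviving gene
#'   selection as a feature; `"forward"` runs [select_feature_modules()].
#' @param cv_select run the five-family cross-validated comparison and
#'   record it (default TRUE).
#' @param cv_k folds for that comparison.
#' @param seed seed for fold assignment and feature selection.
#' @param ... passed to [select_feature_modules()] when
#'   `feature_selection = "forward"`.
#' @return An object of class `mf_model`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_samples = 60, seed = 1))
#' fit <- mf_fit(cohort$expr, cohort$pheno)
#' fit
#' head(predict(fit, cohort$expr))
#' @export
mf_fit <- function(expr, pheno, params = network_params(),
                   gs_min = 0.1, fdr_max = 0.4,
                   min_total = 50, min_fraction = 0.02,
                   lambda = 1, feature_selection = c("all", "forward"),
                   cv_select = TRUE, cv_k = 10, seed = 1L, ...) {
  feature_selection <- match.arg(feature_selection)
  if (expr_scale(expr) == "raw") {
    expr <- filter_genes(expr, min_total = min_total, min_fraction = min_fraction)
    expr <- lognormalize(expr)
  }
  ph <- align_phenotype(pheno, colnames(expr))

  if (is.null(params$power)) {
    st <- pick_soft_threshold(expr, params)
    power <- st$power; fit_table <- st$fit_table
  } else {
    power <- params$power; fit_table <- NULL
  }
  adj <- adjacency_matrix(expr, power, params$network_type)
  tom <- tom_matrix(adj)
  modules <- detect_modules(tom, params, expr = expr)
  eig <- module_eigengenes(expr, modules)
  module_stats <- module_trait_stats(eig, pheno)
  gene_stats <- gene_trait_stats(expr, pheno)
  gene_sets <- select_module_genes(modules, gene_stats, module_stats,
                                   gs_min = gs_min, fdr_max = fdr_max)
  mf_raw <- compute_module_factors(expr, gene_sets)
  mf <- minmax_normalize(mf_raw)

  selection <- NULL
  if (feature_selection == "forward" && ncol(mf$values) > 1) {
    selection <- select_feature_modules(mf, pheno, module_stats,
                                        lambda = lambda, seed = seed, ...)
    selected <- selection$selected
  } else {
    selected <- colnames(mf$values)
  }

  X <- mf$values[, selected, drop = FALSE]
  y01 <- ph$trait
  cv <- NULL
  if (cv_select && nrow(X) >= cv_k) {
    cv <- crossval_model_selection(X, y01, k = cv_k, seed = seed, lambda = lambda)
  }
  classifier <- fit_logistic_l2(X, y01, lambda = lambda)

  structure(list(
    power = power, fit_table = fit_table, modules = modules,
    eigengenes = eig, module_stats = module_stats, gene_stats = gene_stats,
    gene_sets = gene_sets, mf = mf, selected_modules = selected,
    selection = selection, cv = cv, classifier = classifier,
    gene_universe = rownames(expr), pheno = ph,
    config = list(gs_min = gs_min, fdr_max = fdr_max, min_total = min_total,
                  min_fraction = min_fraction, lambda = lambda,
                  feature_selection = feature_selection, seed = seed,
                  params = params),
    call = match.call()),
    class = "mf_model")
}

#' @export
print.mf_model <- function(x, ...) {
  n_mod <- sum(x$module_stats$module != "unassigned")
  cat("Module-factor rejection risk model\n")
  cat(sprintf("  soft-threshold power: %d\n", x$power))
  cat(sprintf("  modules detected: %d (+ unassigned)\n", n_mod))
  cat(sprintf("  feature modules: %s\n", paste(x$selected_modules, collapse = ", ")))
  if (!is.null(x$cv))
    cat(sprintf("  CV-best classifier family: %s\n", x$cv$best_model))
  cat(sprintf("  final model: L2 logistic (lambda = %g)\n", x$config$lambda))
  invisible(x)
}

#' @export
summary.mf_model <- function(object, ...) {
  gt <- mf_group_test(restrict_mf(object$mf, object$selected_modules),
                      phenotype_table(stats::setNames(object$pheno$label,
                                                      object$pheno$sample_id)))
  out <- list(model = object, module_stats = object$module_stats,
              group_tests = gt, cv_table = object$cv$cv_table)
  class(out) <- "summary.mf_model"
  out
}

#' @export
print.summary.mf_model <- function(x, ...) {
  print(x$model)
  cat("\nModule-trait associations:\n")
  print(x$module_stats, row.names = FALSE)
  cat("\nModule factor group tests (R vs NR):\n")
  print(x$group_tests, row.names = FALSE)
  if (!is.null(x$cv_table)) {
    cat("\nCross-validated family accuracies:\n")
    print(x$cv_table, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.mf_model <- function(object, ...) object$classifier$coefficients

#' @keywords internal
#' @noRd
restrict_mf <- function(mf, modules) {
  mf$values <- mf$values[, modules, drop = FALSE]
  if (!is.null(mf$norm_params))
    mf$norm_params <- mf$norm_params[match(modules, mf$norm_params$module), , drop = FALSE]
  if (isTRUE(mf$normalized)) mf <- merge_module_factors(mf)
  mf
}

#' Predict rejection risk for new samples
#'
#' Computes the fitted model's module factors on new expression data (the
#' stored GS weights and min-max parameters are applied unchanged — nothing
#' is re-estimated) and scores samples with the fitted logistic model.
#'
#' @param object an `mf_model`.
#' @param newdata an [expression_matrix()] (raw or lognorm) containing the
#'   model's gene universe.
#' @param type `"prob"` (default) for P(R), `"class"` for thresholded R/NR
#'   labels, `"mf"` for the normalized module factor matrix (with merged
#'   MF_R/MF_NR as attribute `"merged"`).
#' @param threshold classification threshold for `type = "class"`.
#' @param ... unused.
#' @return Named vector of probabilities or labels, or the MF matrix.
#' @export
predict.mf_model <- function(object, newdata, type = c("prob", "class", "mf"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  miss <- setdiff(object$gene_universe, rownames(newdata))
  if (length(miss))
    mf_stop("newdata is missing model gene(s): ",
            paste(utils::head(miss, 5), collapse = ", "),
            if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "")
  newdata <- newdata[object$gene_universe, , drop = FALSE]
  if (expr_scale(newdata) == "raw") newdata <- lognormalize(newdata)
  mf_new <- compute_module_factors(newdata, object$gene_sets)
  mf_new <- apply_minmax(mf_new, object$mf$norm_params)
  mf_new <- restrict_mf(mf_new, object$selected_modules)
  if (type == "mf") {
    out <- mf_new$values
    attr(out, "merged") <- mf_new$merged
    return(out)
  }
  pr <- predict(object$classifier, mf_new$values)
  names(pr) <- rownames(mf_new$values)
  if (type == "prob") pr else ifelse(pr > threshold, "R", "NR")
}

#' @export
fitted.mf_model <- function(object, ...) {
  pr <- predict(object$classifier, object$mf$values[, object$selected_modules, drop = FALSE])
  stats::setNames(pr, rownames(object$mf$values))
}

#' @export
residuals.mf_model <- function(object, ...) {
  object$pheno$trait - fitted(object)
}

#' Risk map: MF_R versus MF_NR
#'
#' Scatter of the merged R-associated factor sum against the NR-associated
#' one, colored by true label. Rejectors are expected to concentrate where
#' MF_R is high and MF_NR low.
#'
#' @param x an `mf_model`.
#' @param newdata optional expression matrix to map instead of the training
#'   cohort.
#' @param pheno labels for `newdata`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mf_model <- function(x, newdata = NULL, pheno = NULL, ...) {
  if (is.null(newdata)) {
    mf <- restrict_mf(x$mf, x$selected_modules)
    merged <- mf$merged
    labels <- x$pheno$label
  } else {
    m <- predict(x, newdata, type = "mf")
    merged <- attr(m, "merged")
    labels <- align_phenotype(pheno, rownames(m))$label
  }
  if (is.null(merged$MF_R) || is.null(merged$MF_NR))
    mf_stop("risk map needs modules of both directions")
  cols <- ifelse(labels == "R", "#d62728", "#1f77b4")
  graphics::plot(merged$MF_R, merged$MF_NR, col = cols, pch = 19,
                 xlab = "MF_R (sum of R-associated module factors)",
                 ylab = "MF_NR (sum of NR-associated module factors)", ...)
  graphics::legend("topright", legend = c("R", "NR"),
                   col = c("#d62728", "#1f77b4"), pch = 19, bty = "n")
  invisible(merged)
}
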