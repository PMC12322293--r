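#' Default run configuration
#'
#' All parameters of a full pipeline run with their defaults. A YAML config
#' file may override any of them; unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    expression = NULL, phenotype = NULL, out_dir = "modfactor_run",
    simulate = NULL,                        # synthetic_config overrides, or NULL
    mode = "strict", n_repeats = 50, test_fraction = 0.2, seed0 = 1L,
    min_total = 50, min_fraction = 0.02,
    fit_target = 0.82, candidate_powers = 1:20, min_module_size = 30,
    merge_cut_height = 0.25, deep_split = 2, network_type = "unsigned",
    gs_min = 0.1, fdr_max = 0.4, lambda = 1,
    feature_selection = "all", cv_select = TRUE, cv_k = 10, threshold = 0.5,
    figures = TRUE)
}

#' Read and validate a run configuration
#'
#' @param path YAML file; keys as in [default_run_config()].
#' @param overrides named list applied on top of the file.
#' @return Completed configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    mf_stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, user)
}

#' Validate expression and phenotype input files
#'
#' Checks performed: readable files, unique gene and sample IDs,
#' non-negative values, no missing entries, every matrix sample labeled,
#' both classes present. Phenotype rows for samples absent from the matrix
#' are only warned about. All failures are collected and reported at once.
#'
#' @param expression_path,phenotype_path input files (see
#'   [read_expression()] / [read_phenotype()]).
#' @return List with `ok` (logical), `errors`, `warnings`.
#' @export
validate_inputs <- function(expression_path, phenotype_path) {
  errors <- character(0); warns <- character(0)
  expr <- tryCatch(read_expression(expression_path),
                   error = function(e) {errors <<- c(errors, conditionMessage(e)); NULL})
  ph <- tryCatch(read_phenotype(phenotype_path),
                 error = function(e) {errors <<- c(errors, conditionMessage(e)); NULL})
  if (!is.null(expr) && !is.null(ph)) {
    missing <- setdiff(colnames(expr), ph$sample_id)
    if (length(missing))
      errors <- c(errors, paste0("phenotype missing matrix sample(s): ",
                                 paste(missing, collapse = ", ")))
    extra <- setdiff(ph$sample_id, colnames(expr))
    if (length(extra))
      warns <- c(warns, paste0("phenotype rows not in matrix (ignored): ",
                               paste(extra, collapse = ", ")))
    common <- intersect(ph$sample_id, colnames(expr))
    if (length(common) && length(unique(ph$label[ph$sample_id %in% common])) < 2)
      errors <- c(errors, "only one class present among matrix samples")
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warns)
}

#' Run the full pipeline end to end
#'
#' simulate (optional) -> validate -> preprocess -> network -> features ->
#' repeated evaluation, with every artifact written to `out_dir`: the
#' filtered matrix, soft-threshold fit table, module assignment, gene and
#' module statistics, MF matrix with merged MF_R/MF_NR, group-test table,
#' per-repeat metrics and medians, figures (metric panel and risk map), a
#' run log listing every decided parameter, and a provenance JSON (config +
#' package version + seeds) from which the run can be reproduced exactly.
#'
#' @param config list from [read_run_config()], or a path to a YAML file.
#' @return Invisibly, a list with `report` (the [run_repeated_pipeline()]
#'   result), `fit` (full-cohort `mf_model`), and `out_dir`.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)

  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(synthetic_config, cfg$simulate)
    cohort <- generate_cohort(sim_cfg)
    write_cohort(cohort, file.path(cfg$out_dir, "synthetic"))
    expr <- cohort$expr; pheno <- cohort$pheno
    logf("simulated cohort: %d genes x %d samples (seed %d)",
         nrow(expr), ncol(expr), sim_cfg$seed)
  } else {
    if (is.null(cfg$expression) || is.null(cfg$phenotype))
      mf_stop("config needs 'expression' and 'phenotype' paths (or 'simulate')")
    v <- validate_inputs(cfg$expression, cfg$phenotype)
    for (w in v$warnings) warning(w, call. = FALSE)
    if (!v$ok) mf_stop("input validation failed:\n  ",
                       paste(v$errors, collapse = "\n  "))
    expr <- read_expression(cfg$expression)
    pheno <- read_phenotype(cfg$phenotype)
  }
  for (key in setdiff(names(cfg), c("expression", "phenotype", "simulate")))
    logf("param %s = %s", key, paste(format(cfg[[key]]), collapse = ","))

  np <- network_params(candidate_powers = cfg$candidate_powers,
                       fit_target = cfg$fit_target,
                       min_module_size = cfg$min_module_size,
                       merge_cut_height = cfg$merge_cut_height,
                       deep_split = cfg$deep_split,
                       network_type = cfg$network_type)

  # full-cohort fit for the descriptive artifacts
  fit <- mf_fit(expr, pheno, params = np, gs_min = cfg$gs_min,
                fdr_max = cfg$fdr_max, min_total = cfg$min_total,
                min_fraction = cfg$min_fraction, lambda = cfg$lambda,
                feature_selection = cfg$feature_selection,
                cv_select = cfg$cv_select, cv_k = cfg$cv_k, seed = cfg$seed0)
  logf("soft-threshold power: %d", fit$power)
  logf("modules: %s", paste(unique(unclass(fit$modules)), collapse = ", "))

  out <- function(f) file.path(cfg$out_dir, f)
  filt <- filter_genes(expr, cfg$min_total, cfg$min_fraction)
  write_expression(filt, out("filtered_expression.tsv"))
  if (!is.null(fit$fit_table))
    utils::write.table(fit$fit_table, out("soft_threshold.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(unclass(fit$modules)),
               module = as.character(unclass(fit$modules))),
    out("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$gene_stats, out("gene_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$module_stats, out("module_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mf_sel <- restrict_mf(fit$mf, fit$selected_modules)
  mf_out <- data.frame(sample_id = rownames(mf_sel$values), mf_sel$values,
                       mf_sel$merged, check.names = FALSE)
  utils::write.table(mf_out, out("module_factors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mf_group_test(mf_sel, pheno), out("mf_group_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pc <- pipeline_config(mode = cfg$mode, n_repeats = cfg$n_repeats,
                        test_fraction = cfg$test_fraction, seed0 = cfg$seed0,
                        gs_min = cfg$gs_min, fdr_max = cfg$fdr_max,
                        min_total = cfg$min_total, min_fraction = cfg$min_fraction,
                        lambda = cfg$lambda, feature_selection = cfg$feature_selection,
                        cv_select = cfg$cv_select, cv_k = cfg$cv_k,
                        threshold = cfg$threshold, params = np)
  report <- run_repeated_pipeline(expr, pheno, pc)
  utils::write.table(report$per_repeat, out("metrics_per_repeat.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(medians = as.list(report$medians), pooled_auc = report$pooled_auc,
         n_repeats = pc$n_repeats, mode = pc$mode,
         failed_repeats = length(report$failed)),
    out("evaluation_summary.json"), auto_unbox = TRUE, digits = NA)
  logf("median AUC: %.4f", report$medians[["auc"]])

  if (isTRUE(cfg$figures)) {
    grDevices::png(out("metric_panel.png"), width = 700, height = 500)
    plot(report, main = sprintf("Test metrics over %d repeats (%s mode)",
                                pc$n_repeats, pc$mode))
    grDevices::dev.off()
    has_both <- !is.null(mf_sel$merged$MF_R) && !is.null(mf_sel$merged$MF_NR)
    if (has_both) {
      grDevices::png(out("risk_map.png"), width = 600, height = 600)
      plot(fit, main = "Rejection risk map")
      grDevices::dev.off()
    }
  }
  jsonlite::write_json(
    list(package = "modfactor",
         version = as.character(utils::packageVersion("modfactor")),
         config = cfg[setdiff(names(cfg), c("expression", "phenotype"))],
         inputs = list(expression = cfg$expression, phenotype = cfg$phenotype)),
    out("provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, fit = fit, out_dir = cfg$out_dir))
}
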