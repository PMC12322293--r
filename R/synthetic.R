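#' Configuration for a synthetic expression cohort
#'
#' Describes a cohort with planted trait-linked co-expression modules. Each
#' module is driven by a latent factor `f = delta * t + N(0, 1)` where `t` is
#' the trait code (+1 for rejectors, -1 for non-rejectors), so `delta` is the
#' trait effect on the module's shared factor: positive deltas plant
#' R-associated modules, negative deltas NR-associated ones, and `delta = 0`
#' plants a co-expressed but trait-null module. Background genes carry no
#' factor at all. Log2-scale expression is
#' `baseline + loading * f + noise_sd * N(0, 1)` and the emitted values are
#' `2^x`, giving the positively skewed, non-negative FPKM-like marginals the
#' downstream filters expect.
#'
#' The defaults describe the cohort used throughout the package's own
#' validation: 100 samples at 40% rejectors, three R-associated and two
#' NR-associated modules of 40 genes at `delta = 0.8`, 200 background genes,
#' loadings U(0.5, 0.9) and unit noise.
#'
#' @param n_samples number of samples.
#' @param r_fraction fraction of samples labeled R, in (0, 1).
#' @param modules list of `list(size =, delta =)` entries.
#' @param n_background number of unstructured background genes.
#' @param loading_range length-2 numeric in (0, 1], uniform range for gene
#'   loadings on the module factor.
#' @param noise_sd gene-level noise standard deviation (log2 scale).
#' @param baseline_mean,baseline_sd distribution of per-gene log2 baselines.
#' @param seed integer seed; equal seeds give bitwise-identical cohorts.
#' @return A validated `synthetic_config` list.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_samples = 100,
                             r_fraction = 0.4,
                             modules = list(
                               list(size = 40, delta = 0.8),
                               list(size = 40, delta = 0.8),
                               list(size = 40, delta = 0.8),
                               list(size = 40, delta = -0.8),
                               list(size = 40, delta = -0.8)),
                             n_background = 200,
                             loading_range = c(0.5, 0.9),
                             noise_sd = 1,
                             baseline_mean = 3,
                             baseline_sd = 2,
                             seed = 1L) {
  cfg <- list(n_samples = n_samples, r_fraction = r_fraction, modules = modules,
              n_background = n_background, loading_range = loading_range,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' @keywords internal
#' @noRd
validate_synthetic_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) mf_stop("invalid synthetic config: '", field, "' ", msg)
  chk(is.numeric(cfg$n_samples) && length(cfg$n_samples) == 1 && cfg$n_samples >= 4 &&
        cfg$n_samples == round(cfg$n_samples), "n_samples", "must be an integer >= 4")
  chk(is.numeric(cfg$r_fraction) && cfg$r_fraction > 0 && cfg$r_fraction < 1,
      "r_fraction", "must lie in (0, 1)")
  n_r <- round(cfg$n_samples * cfg$r_fraction)
  chk(n_r >= 2 && cfg$n_samples - n_r >= 2, "r_fraction",
      "must yield at least 2 samples per class")
  chk(is.list(cfg$modules), "modules", "must be a list of list(size=, delta=)")
  for (m in cfg$modules) {
    chk(is.list(m) && all(c("size", "delta") %in% names(m)), "modules",
        "entries need 'size' and 'delta'")
    chk(is.numeric(m$size) && m$size >= 1 && m$size == round(m$size), "modules",
        "sizes must be positive integers")
    chk(is.numeric(m$delta) && length(m$delta) == 1, "modules", "deltas must be numeric")
  }
  chk(is.numeric(cfg$n_background) && cfg$n_background >= 0 &&
        cfg$n_background == round(cfg$n_background), "n_background",
      "must be a non-negative integer")
  total <- sum(vapply(cfg$modules, function(m) m$size, numeric(1))) + cfg$n_background
  chk(total > 0, "modules", "plus n_background must give at least one gene")
  chk(is.numeric(cfg$loading_range) && length(cfg$loading_range) == 2 &&
        cfg$loading_range[1] > 0 && cfg$loading_range[2] <= 1 &&
        cfg$loading_range[1] <= cfg$loading_range[2], "loading_range",
      "must be (low, high) with 0 < low <= high <= 1")
  chk(is.numeric(cfg$noise_sd) && cfg$noise_sd > 0, "noise_sd", "must be positive")
  chk(is.numeric(cfg$baseline_mean), "baseline_mean", "must be numeric")
  chk(is.numeric(cfg$baseline_sd) && cfg$baseline_sd >= 0, "baseline_sd",
      "must be non-negative")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed", "must be an integer")
  invisible(cfg)
}

#' Generate a synthetic cohort with planted trait-linked modules
#'
#' Draws an FPKM-like gene-by-sample matrix, binary rejection labels, and a
#' ground-truth record (planted module of every gene, module deltas, gene
#' loadings) for parameter-recovery testing of the downstream network, module
#' factor, and classification stages.
#'
#' Labels are assigned by exact stratification (`round(n_samples * r_fraction)`
#' rejectors) and then shuffled under the seed, so class balance is controlled
#' exactly. All randomness flows from `config$seed`; equal configurations give
#' bitwise-identical outputs.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `expr` ([expression_matrix()] on the raw
#'   scale), `pheno` ([phenotype_table()]), and `truth` (list with
#'   `gene_module`, `module_delta`, `gene_loading`, `labels`).
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   n_samples = 60, modules = list(list(size = 50, delta = 0.8),
#'                                  list(size = 50, delta = -0.8)),
#'   n_background = 200, seed = 1))
#' dim(cohort$expr)
#' table(cohort$pheno$label)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  validate_synthetic_config(config)

  set.seed(as.integer(config$seed))
  n <- as.integer(config$n_samples)
  n_r <- as.integer(round(n * config$r_fraction))
  labels <- sample(c(rep("R", n_r), rep("NR", n - n_r)))
  sample_ids <- sprintf("S%03d", seq_len(n))
  names(labels) <- sample_ids
  t_code <- ifelse(labels == "R", 1, -1)

  sizes <- vapply(config$modules, function(m) m$size, numeric(1))
  deltas <- vapply(config$modules, function(m) m$delta, numeric(1))
  n_mod_genes <- sum(sizes)
  n_genes <- as.integer(n_mod_genes + config$n_background)

  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  gene_module <- c(rep(seq_along(sizes), times = sizes),
                   rep("background", config$n_background))
  gene_module <- as.character(gene_module)
  names(gene_module) <- gene_ids

  baseline <- stats::rnorm(n_genes, config$baseline_mean, config$baseline_sd)
  loading <- stats::runif(n_genes, config$loading_range[1], config$loading_range[2])
  loading[gene_module == "background"] <- 0
  names(loading) <- gene_ids

  # latent factor per module: delta * t + standard normal, one row per module
  factors <- matrix(stats::rnorm(length(sizes) * n), nrow = length(sizes))
  factors <- factors + outer(deltas, t_code)

  x <- matrix(stats::rnorm(n_genes * n, sd = config$noise_sd), nrow = n_genes) + baseline
  if (length(sizes)) {
    midx <- rep(seq_along(sizes), times = sizes)
    x[seq_len(n_mod_genes), ] <- x[seq_len(n_mod_genes), ] +
      loading[seq_len(n_mod_genes)] * factors[midx, , drop = FALSE]
  }
  values <- 2^x
  dimnames(values) <- list(gene_ids, sample_ids)

  truth <- list(gene_module = gene_module,
                module_delta = stats::setNames(deltas, as.character(seq_along(deltas))),
                gene_loading = loading,
                labels = labels)
  list(expr = expression_matrix(values, "raw"),
       pheno = phenotype_table(labels),
       truth = truth)
}

#' Write a synthetic cohort to plain-text files
#'
#' Expression as TSV (genes in rows, header = sample IDs), phenotype as
#' 2-column TSV, ground truth as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                phenotype = file.path(dir, "phenotype.tsv"),
                truth = file.path(dir, "truth.json"))
  write_expression(cohort$expr, paths$expression)
  write_phenotype(cohort$pheno, paths$phenotype)
  jsonlite::write_json(cohort$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
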