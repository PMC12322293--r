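#' Select module genes by gene significance and FDR
#'
#' Direction-aligned gene selection for module factor construction. For an
#' R-associated module (positive eigengene-trait correlation) a gene is kept
#' when `GS > gs_min` and `fdr < fdr_max`; for an NR-associated module the
#' sign flips (`GS < -gs_min`), because with the single R = 1 / NR = 0 trait
#' coding an NR-linked gene carries a negative GS. Modules left empty are
#' dropped with a warning; if every candidate module empties, an error asks
#' for threshold relaxation.
#'
#' @param modules a `module_assignment` from [detect_modules()].
#' @param gene_stats data frame from [gene_trait_stats()].
#' @param module_stats data frame from [module_trait_stats()]; its `module`
#'   column defines the candidate modules (the "unassigned" group included).
#' @param gs_min GS magnitude threshold (default 0.1, exclusive).
#' @param fdr_max FDR threshold (default 0.4, exclusive).
#' @return A named list (`module_gene_sets`), one data frame
#'   (`gene_id`, `gs`) per surviving module, with a `direction` attribute
#'   (named character vector module -> R_positive/NR_positive).
#' @export
select_module_genes <- function(modules, gene_stats, module_stats,
                                gs_min = 0.1, fdr_max = 0.4) {
  labs <- unclass(modules)
  stats_idx <- stats::setNames(seq_len(nrow(gene_stats)), gene_stats$gene_id)
  out <- list()
  dirs <- character(0)
  for (i in seq_len(nrow(module_stats))) {
    mod <- module_stats$module[i]
    dir <- module_stats$direction[i]
    genes <- names(labs)[labs == mod]
    idx <- stats_idx[genes]
    if (anyNA(idx))
      mf_stop("gene_stats does not cover module ", mod, " genes: ",
              paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
    st <- gene_stats[idx, , drop = FALSE]
    keep <- if (dir == "R_positive") st$gs > gs_min else st$gs < -gs_min
    keep <- keep & st$fdr < fdr_max
    if (!any(keep)) {
      warning("module ", mod, " retains no genes at gs_min=", gs_min,
              ", fdr_max=", fdr_max, "; dropped", call. = FALSE)
      next
    }
    out[[mod]] <- data.frame(gene_id = st$gene_id[keep], gs = st$gs[keep],
                             stringsAsFactors = FALSE)
    dirs[mod] <- dir
  }
  if (!length(out))
    mf_stop("no module retains any gene at gs_min=", gs_min, ", fdr_max=",
            fdr_max, "; relax the thresholds")
  structure(out, direction = dirs, class = "module_gene_sets")
}

#' Surviving gene counts over a threshold grid
#'
#' For every (gs_min, fdr_max) pair and every module, the number of genes
#' that would survive selection — the diagnostic used to justify the default
#' thresholds. Without `module_stats` the count is direction-agnostic
#' (`|GS| > gs_min`); with it, the direction-aligned rule of
#' [select_module_genes()] is applied, making any grid cell exactly
#' consistent with that function.
#'
#' @param gene_stats data frame from [gene_trait_stats()].
#' @param modules a `module_assignment`.
#' @param gs_grid,fdr_grid numeric vectors of thresholds.
#' @param module_stats optional [module_trait_stats()] output.
#' @return Data frame: `gs_min`, `fdr_max`, `module`, `n_genes`.
#' @export
threshold_sweep <- function(gene_stats, modules, gs_grid, fdr_grid,
                            module_stats = NULL) {
  if (!length(gs_grid) || !length(fdr_grid)) mf_stop("threshold grids must be non-empty")
  labs <- unclass(modules)
  mods <- unique(labs)
  dirs <- NULL
  if (!is.null(module_stats))
    dirs <- stats::setNames(module_stats$direction, module_stats$module)
  st <- gene_stats[match(names(labs), gene_stats$gene_id), , drop = FALSE]
  grid <- expand.grid(gs_min = gs_grid, fdr_max = fdr_grid, module = mods,
                      stringsAsFactors = FALSE)
  grid$n_genes <- vapply(seq_len(nrow(grid)), function(r) {
    in_mod <- labs == grid$module[r]
    gs <- st$gs[in_mod]; fdr <- st$fdr[in_mod]
    keep <- if (is.null(dirs)) abs(gs) > grid$gs_min[r]
            else if (dirs[[grid$module[r]]] == "R_positive") gs > grid$gs_min[r]
            else gs < -grid$gs_min[r]
    sum(keep & fdr < grid$fdr_max[r])
  }, numeric(1))
  grid
}

#' Compute module factors
#'
#' The module factor of sample s for a module is the gene-significance
#' weighted expression sum `MF(s) = sum_i GS_i * EX_i(s)` over the module's
#' selected genes — a one-number-per-module feature in which each gene
#' contributes proportionally to how strongly it tracks the trait.
#'
#' @param expr lognorm-scale [expression_matrix()] containing every selected
#'   gene.
#' @param gene_sets a `module_gene_sets` from [select_module_genes()].
#' @return An `mf_matrix`: list with `values` (samples x modules, raw MF),
#'   `direction`, `normalized = FALSE`.
#' @export
compute_module_factors <- function(expr, gene_sets) {
  assert_scale(expr, "lognorm", "compute_module_factors")
  if (!length(gene_sets)) mf_stop("empty gene_sets")
  vals <- sapply(names(gene_sets), function(mod) {
    gs_tab <- gene_sets[[mod]]
    miss <- setdiff(gs_tab$gene_id, rownames(expr))
    if (length(miss))
      mf_stop("gene(s) in module ", mod, " absent from the matrix: ",
              paste(utils::head(miss, 5), collapse = ", "))
    drop(crossprod(unclass(expr)[gs_tab$gene_id, , drop = FALSE], gs_tab$gs))
  })
  vals <- matrix(vals, nrow = ncol(expr),
                 dimnames = list(colnames(expr), names(gene_sets)))
  structure(list(values = vals,
                 direction = attr(gene_sets, "direction"),
                 normalized = FALSE, norm_params = NULL, merged = NULL),
            class = "mf_matrix")
}

#' @export
print.mf_matrix <- function(x, ...) {
  cat(sprintf("mf_matrix: %d samples x %d modules (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Min-max normalize module factors
#'
#' Per module, `(x - min) / (max - min)` with the minimum and maximum taken
#' over `fit_samples` only. Values for samples outside the fit set use the
#' same affine map and may fall outside \[0, 1\]; they are deliberately not
#' clipped, so distribution shift between fit and held-out samples stays
#' visible. A module constant on the fit set normalizes to all zeros with a
#' warning. This step removes the dependence of MF magnitude on module size
#' and expression level so that modules are comparable and summable.
#'
#' @param mf an `mf_matrix` (raw).
#' @param fit_samples sample IDs the min/max are estimated from (default:
#'   all samples in `mf`).
#' @return The `mf_matrix` with normalized `values` and `norm_params` (data
#'   frame module/min/max) recorded.
#' @export
minmax_normalize <- function(mf, fit_samples = NULL) {
  fit_samples <- fit_samples %||% rownames(mf$values)
  miss <- setdiff(fit_samples, rownames(mf$values))
  if (length(miss)) mf_stop("fit_samples absent from MF matrix: ",
                            paste(utils::head(miss, 5), collapse = ", "))
  fit <- mf$values[fit_samples, , drop = FALSE]
  params <- data.frame(module = colnames(mf$values),
                       min = apply(fit, 2, min), max = apply(fit, 2, max),
                       stringsAsFactors = FALSE, row.names = NULL)
  apply_minmax(mf, params)
}

#' @rdname minmax_normalize
#' @param params previously fitted `norm_params` (e.g. from the training
#'   cohort), applied unchanged.
#' @export
apply_minmax <- function(mf, params) {
  stopifnot(identical(params$module, colnames(mf$values)))
  vals <- mf$values
  for (j in seq_len(ncol(vals))) {
    rng <- params$max[j] - params$min[j]
    if (rng == 0) {
      warning("module ", params$module[j],
              " is constant on the fit set; normalized to 0", call. = FALSE)
      vals[, j] <- 0
    } else {
      vals[, j] <- (vals[, j] - params$min[j]) / rng
    }
  }
  out <- mf
  out$values <- vals
  out$normalized <- TRUE
  out$norm_params <- params
  merge_module_factors(out)
}

#' Merge module factors into MF_R and MF_NR
#'
#' `MF_R(s)` is the sum of the normalized factors of all R-associated
#' modules and `MF_NR(s)` the same over NR-associated modules — the two
#' coordinates of the rejection risk map. A direction with no module yields
#' an absent (NULL) column, not a zero one.
#'
#' @param mf a normalized `mf_matrix` with directions set.
#' @return The `mf_matrix` with a `merged` data frame (columns among `MF_R`,
#'   `MF_NR`).
#' @export
merge_module_factors <- function(mf) {
  if (!isTRUE(mf$normalized))
    mf_stop("merge requires normalized module factors")
  if (is.null(mf$direction)) mf_stop("module directions are not set")
  dirs <- mf$direction[colnames(mf$values)]
  merged <- data.frame(row.names = rownames(mf$values))
  if (any(dirs == "R_positive"))
    merged$MF_R <- rowSums(mf$values[, dirs == "R_positive", drop = FALSE])
  if (any(dirs == "NR_positive"))
    merged$MF_NR <- rowSums(mf$values[, dirs == "NR_positive", drop = FALSE])
  mf$merged <- merged
  mf
}

#' Compare module factors between R and NR samples
#'
#' Two-sided Welch (unequal-variance) t-tests of every module factor and of
#' the merged MF_R/MF_NR between rejectors and non-rejectors, with
#' Holm-Sidak multiple-testing adjustment and conventional significance
#' stars.
#'
#' @param mf an `mf_matrix` (raw or normalized; merged columns are included
#'   when present).
#' @param pheno a [phenotype_table()].
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return Data frame: `feature`, `t`, `p`, `p_adj`, `stars`, group means.
#' @export
mf_group_test <- function(mf, pheno, var_equal = FALSE) {
  feats <- mf$values
  if (!is.null(mf$merged) && ncol(mf$merged))
    feats <- cbind(feats, as.matrix(mf$merged))
  ph <- align_phenotype(pheno, rownames(feats))
  if (min(table(ph$label)) < 2) mf_stop("need >= 2 samples per class for t-tests")
  res <- lapply(colnames(feats), function(f) {
    x <- feats[ph$label == "R", f]; y <- feats[ph$label == "NR", f]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # identical constant groups: no evidence of difference by convention
      tt <- list(statistic = 0, p.value = as.numeric(mean(x) == mean(y)))
      if (mean(x) != mean(y)) mf_stop("degenerate zero-variance groups differ for ", f)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    data.frame(feature = f, t = unname(tt$statistic), p = tt$p.value,
               mean_R = mean(x), mean_NR = mean(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p_adjust_holm_sidak(out$p)
  out$stars <- p_stars(out$p_adj)
  out[, c("feature", "t", "p", "p_adj", "stars", "mean_R", "mean_NR")]
}

#' Forward selection of feature modules
#'
#' Automates the choice of which candidate modules become classifier
#' features, following two gates and a balance rule. A candidate module must
#' (i) be significantly trait-associated — Holm-Sidak-adjusted eigengene
#' trait p below `alpha`, an unbiased criterion because eigengenes are
#' computed before any gene-level selection — and (ii) individually separate
#' R from NR (Welch p < `alpha` on its normalized factor). Survivors are
#' ranked by module-trait p within each direction and added alternately from
#' the two directions, keeping the R/NR feature counts within one of each
#' other. By default all gated, balance-admissible candidates are kept and
#' the cross-validated AUC trace over feature counts is returned as the
#' justification sweep; setting `epsilon` additionally stops growth (after
#' the minimum viable set of one module per available direction) at the
#' smallest count where adding one more feature improves mean CV AUC by less
#' than `epsilon`.
#'
#' @param mf normalized `mf_matrix` over all candidate modules.
#' @param pheno a [phenotype_table()].
#' @param module_stats data frame from [module_trait_stats()] covering the
#'   candidates.
#' @param max_features optional hard cap on the selection size.
#' @param epsilon optional minimum mean-CV-AUC improvement to justify one
#'   more feature; `NULL` (default) disables the AUC-gain stop.
#' @param alpha significance gate for both criteria (default 0.05).
#' @param cv_folds folds for the AUC trace (default 5).
#' @param lambda ridge penalty of the trace classifier.
#' @param seed fold-assignment seed.
#' @return List with `selected` (module names), `direction_counts`, and
#'   `trace` (data frame n_features / module / cv_auc, the feature-count
#'   sweep).
#' @export
select_feature_modules <- function(mf, pheno, module_stats,
                                   max_features = NULL, epsilon = NULL,
                                   alpha = 0.05, cv_folds = 5, lambda = 1,
                                   seed = 1L) {
  if (!isTRUE(mf$normalized)) mf_stop("candidates must be normalized")
  ph <- align_phenotype(pheno, rownames(mf$values))
  gt <- mf_group_test(mf, pheno)
  cand <- colnames(mf$values)
  ms_idx <- match(cand, module_stats$module)
  if (anyNA(ms_idx)) mf_stop("module_stats does not cover all candidates")
  trait_p_adj <- p_adjust_holm_sidak(module_stats$p)[ms_idx]
  pass <- cand[trait_p_adj < alpha & gt$p[match(cand, gt$feature)] < alpha]
  if (!length(pass))
    mf_stop("no candidate module is trait-associated and separates R from NR at p < ", alpha)
  mp <- stats::setNames(module_stats$p, module_stats$module)
  dir <- mf$direction
  r_mods <- pass[dir[pass] == "R_positive"]
  nr_mods <- pass[dir[pass] == "NR_positive"]
  r_mods <- r_mods[order(mp[r_mods])]
  nr_mods <- nr_mods[order(mp[nr_mods])]

  # interleave, starting from the direction whose best candidate is stronger
  order_out <- character(0)
  i_r <- i_nr <- 0L
  r_first <- length(r_mods) > 0 &&
    (length(nr_mods) == 0 || mp[r_mods[1]] <= mp[nr_mods[1]])
  take_r <- r_first
  while (i_r < length(r_mods) || i_nr < length(nr_mods)) {
    can_r <- i_r < length(r_mods) && (i_r - i_nr) < 1L
    can_nr <- i_nr < length(nr_mods) && (i_nr - i_r) < 1L
    if (!can_r && !can_nr) break          # balance rule exhausted
    if (take_r && can_r) { i_r <- i_r + 1L; order_out <- c(order_out, r_mods[i_r]) }
    else if (!take_r && can_nr) { i_nr <- i_nr + 1L; order_out <- c(order_out, nr_mods[i_nr]) }
    else if (can_r) { i_r <- i_r + 1L; order_out <- c(order_out, r_mods[i_r]) }
    else { i_nr <- i_nr + 1L; order_out <- c(order_out, nr_mods[i_nr]) }
    take_r <- !take_r
  }
  if (!is.null(max_features)) order_out <- utils::head(order_out, max_features)

  cv_auc <- function(cols) {
    X <- mf$values[, cols, drop = FALSE]
    y01 <- ph$trait
    fold <- stratified_folds(y01, cv_folds, seed)
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      if (length(unique(y01[tr])) < 2 || length(unique(y01[!tr])) < 2) return(NA_real_)
      fit <- fit_logistic_l2(X[tr, , drop = FALSE], y01[tr], lambda = lambda)
      rank_auc(predict(fit, X[!tr, , drop = FALSE]), y01[!tr])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  trace_auc <- vapply(seq_along(order_out), function(c) cv_auc(order_out[seq_len(c)]),
                      numeric(1))
  n_sel <- length(order_out)
  if (!is.null(epsilon)) {
    min_viable <- min(length(order_out),
                      (length(r_mods) > 0) + (length(nr_mods) > 0))
    for (c in seq(min_viable, length(order_out))) {
      if (c == length(order_out)) { n_sel <- c; break }
      if (trace_auc[c + 1] - trace_auc[c] < epsilon) { n_sel <- c; break }
    }
  }
  selected <- order_out[seq_len(n_sel)]
  list(selected = selected,
       direction_counts = table(factor(dir[selected],
                                       levels = c("R_positive", "NR_positive"))),
       trace = data.frame(n_features = seq_along(order_out),
                          module = order_out, cv_auc = trace_auc))
}
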