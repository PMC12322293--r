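# A small hand-built stats world used across the selection tests: two
# modules with known directions and a gene stats table under our control.
fixture_world <- function() {
  genes <- sprintf("g%02d", 1:6)
  labs <- setNames(c("mA", "mA", "mA", "mB", "mB", "mB"), genes)
  modules <- structure(labs, class = "module_assignment")
  gene_stats <- data.frame(
    gene_id = genes,
    gs = c(0.3, 0.05, 0.3, -0.2, -0.4, 0.25),
    p = c(0.01, 0.5, 0.02, 0.05, 0.001, 0.04),
    fdr = c(0.1, 0.1, 0.5, 0.2, 0.01, 0.39))
  module_stats <- data.frame(module = c("mA", "mB"),
                             eigengene_cor = c(0.6, -0.5),
                             p = c(0.001, 0.01),
                             direction = c("R_positive", "NR_positive"))
  list(modules = modules, gene_stats = gene_stats, module_stats = module_stats)
}

test_that("gene selection applies direction-aligned GS and FDR thresholds", {
  w <- fixture_world()
  sets <- select_module_genes(w$modules, w$gene_stats, w$module_stats)
  # mA (R_positive): g01 kept (0.3 > 0.1, 0.1 < 0.4); g02 fails GS; g03 fails FDR
  expect_identical(sets$mA$gene_id, "g01")
  # mB (NR_positive): g04 kept (GS -0.2 < -0.1, fdr 0.2); g05 kept; g06 wrong sign
  expect_identical(sets$mB$gene_id, c("g04", "g05"))
  expect_identical(attr(sets, "direction"),
                   c(mA = "R_positive", mB = "NR_positive"))

  # fdr_max = 0.05 empties mA (its only passing gene has fdr 0.1)
  expect_warning(
    sets2 <- select_module_genes(w$modules, w$gene_stats, w$module_stats,
                                 fdr_max = 0.05),
    "mA")
  expect_named(sets2, "mB")
  suppressWarnings(
    expect_error(select_module_genes(w$modules, w$gene_stats, w$module_stats,
                                     gs_min = 0.9), "relax"))
})

test_that("gene selection equals a brute-force predicate oracle", {
  set.seed(33)
  n <- 60
  genes <- sprintf("g%03d", 1:n)
  labs <- setNames(sample(c("m1", "m2", "unassigned"), n, replace = TRUE), genes)
  modules <- structure(labs, class = "module_assignment")
  gene_stats <- data.frame(gene_id = genes, gs = runif(n, -1, 1),
                           p = runif(n), fdr = runif(n))
  module_stats <- data.frame(module = c("m1", "m2", "unassigned"),
                             eigengene_cor = c(0.4, -0.3, 0.1),
                             p = c(0.01, 0.02, 0.6),
                             direction = c("R_positive", "NR_positive", "R_positive"))
  sets <- suppressWarnings(select_module_genes(modules, gene_stats, module_stats,
                                               gs_min = 0.2, fdr_max = 0.5))
  for (m in names(sets)) {
    dir <- module_stats$direction[module_stats$module == m]
    expected <- character(0)
    for (g in genes[labs == m]) {
      st <- gene_stats[gene_stats$gene_id == g, ]
      ok <- if (dir == "R_positive") st$gs > 0.2 else st$gs < -0.2
      if (ok && st$fdr < 0.5) expected <- c(expected, g)
    }
    expect_identical(sets[[m]]$gene_id, expected)
  }
})

test_that("threshold sweep counts are monotone and consistent with selection", {
  set.seed(14)
  n <- 80
  genes <- sprintf("g%03d", 1:n)
  labs <- setNames(rep(c("m1", "m2"), each = 40), genes)
  modules <- structure(labs, class = "module_assignment")
  gene_stats <- data.frame(gene_id = genes, gs = runif(n, -1, 1),
                           p = runif(n), fdr = runif(n, 0.001, 0.999))
  sweep <- threshold_sweep(gene_stats, modules,
                           gs_grid = seq(0, 0.4, 0.1), fdr_grid = seq(0.2, 1, 0.2))
  # no filtering at the loosest corner: |gs| > 0 and fdr < 1 keep everything
  loose <- sweep[sweep$gs_min == 0 & sweep$fdr_max == 1, ]
  expect_equal(sort(loose$n_genes), c(40L, 40L))
  for (m in c("m1", "m2")) {
    grid <- sweep[sweep$module == m, ]
    for (fm in unique(grid$fdr_max)) {
      counts <- grid$n_genes[grid$fdr_max == fm][order(grid$gs_min[grid$fdr_max == fm])]
      expect_true(all(diff(counts) <= 0))
    }
    for (gm in unique(grid$gs_min)) {
      counts <- grid$n_genes[grid$gs_min == gm][order(grid$fdr_max[grid$gs_min == gm])]
      expect_true(all(diff(counts) >= 0))
    }
  }
  # direction-aligned sweep cell equals select_module_genes on that module
  module_stats <- data.frame(module = c("m1", "m2"),
                             eigengene_cor = c(0.5, -0.5), p = c(0.01, 0.01),
                             direction = c("R_positive", "NR_positive"))
  sweep_dir <- threshold_sweep(gene_stats, modules, 0.1, 0.4, module_stats)
  sets <- suppressWarnings(select_module_genes(modules, gene_stats, module_stats,
                                               0.1, 0.4))
  for (m in names(sets))
    expect_equal(sweep_dir$n_genes[sweep_dir$module == m], nrow(sets[[m]]))
})

test_that("module factors are the GS-weighted expression sums", {
  e1 <- expression_matrix(matrix(4, 1, 1, dimnames = list("g1", "s1")), "lognorm")
  gs1 <- structure(list(m1 = data.frame(gene_id = "g1", gs = 0.5)),
                   direction = c(m1 = "R_positive"), class = "module_gene_sets")
  expect_equal(unname(compute_module_factors(e1, gs1)$values[1, 1]), 2.0)

  e2 <- expression_matrix(matrix(c(2, 3), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
                          "lognorm")
  gs2 <- structure(list(m1 = data.frame(gene_id = c("g1", "g2"), gs = c(0.2, -0.1))),
                   direction = c(m1 = "R_positive"), class = "module_gene_sets")
  expect_equal(unname(compute_module_factors(e2, gs2)$values[1, 1]), 0.1)

  # 30-gene fixture vs loop oracle; invariance under gene reordering
  e <- random_expr(30, 8, seed = 50)
  ord <- sample(rownames(e))
  gs_tab <- data.frame(gene_id = ord, gs = runif(30, -1, 1))
  sets <- structure(list(mod = gs_tab), direction = c(mod = "R_positive"),
                    class = "module_gene_sets")
  mf <- compute_module_factors(e, sets)
  for (s in colnames(e)) {
    acc <- 0
    for (i in seq_len(nrow(gs_tab)))
      acc <- acc + gs_tab$gs[i] * unclass(e)[gs_tab$gene_id[i], s]
    expect_equal(mf$values[s, "mod"], acc, tolerance = 1e-12)
  }
  sets_sorted <- structure(list(mod = gs_tab[order(gs_tab$gene_id), ]),
                           direction = c(mod = "R_positive"),
                           class = "module_gene_sets")
  expect_equal(compute_module_factors(e, sets_sorted)$values, mf$values,
               tolerance = 1e-12)

  bad <- structure(list(mod = data.frame(gene_id = "nope", gs = 1)),
                   direction = c(mod = "R_positive"), class = "module_gene_sets")
  expect_error(compute_module_factors(e, bad), "nope")
})

mf_from_values <- function(values, direction) {
  structure(list(values = values, direction = direction,
                 normalized = FALSE, norm_params = NULL, merged = NULL),
            class = "mf_matrix")
}

test_that("min-max normalization maps the fit set to [0,1] and extrapolates affinely", {
  v <- matrix(c(1, 3, 5, 6), 4, 1,
              dimnames = list(paste0("s", 1:4), "m1"))
  mf <- mf_from_values(v, c(m1 = "R_positive"))
  out <- minmax_normalize(mf, fit_samples = paste0("s", 1:3))
  expect_equal(unname(out$values[, 1]), c(0, 0.5, 1, 1.25))
  expect_equal(out$norm_params$min, 1)
  expect_equal(out$norm_params$max, 5)

  const <- mf_from_values(matrix(2, 3, 1, dimnames = list(paste0("s", 1:3), "m1")),
                          c(m1 = "R_positive"))
  expect_warning(outc <- minmax_normalize(const), "constant")
  expect_true(all(outc$values == 0))
})

test_that("normalization removes a global scaling of the weighted-sum factors", {
  e <- random_expr(12, 10, seed = 61)
  gs_tab <- data.frame(gene_id = rownames(e), gs = runif(12, -1, 1))
  sets <- structure(list(mod = gs_tab), direction = c(mod = "R_positive"),
                    class = "module_gene_sets")
  mf1 <- compute_module_factors(e, sets)
  e3 <- expression_matrix(unclass(e) * 3, "lognorm")
  mf3 <- compute_module_factors(e3, sets)
  expect_equal(mf3$values, 3 * mf1$values, tolerance = 1e-12)
  expect_equal(minmax_normalize(mf3)$values, minmax_normalize(mf1)$values,
               tolerance = 1e-12)
})

test_that("merged MF_R / MF_NR are the direction-partitioned sums", {
  v <- matrix(c(0.2, 0.1, 0.7, 0.3, 0.4, 0.9), 1, 6,
              dimnames = list("s1", paste0("m", 1:6)))
  dirs <- setNames(c("R_positive", "NR_positive", "R_positive",
                     "NR_positive", "R_positive", "NR_positive"), paste0("m", 1:6))
  mf <- mf_from_values(v, dirs)
  mf$normalized <- TRUE
  out <- merge_module_factors(mf)
  expect_equal(out$merged$MF_R, 0.2 + 0.7 + 0.4)
  expect_equal(out$merged$MF_NR, 0.1 + 0.3 + 0.9)

  # a single NR module: MF_NR equals it; MF_R is absent, not zero
  one <- mf_from_values(matrix(c(0.4, 0.6), 2, 1,
                               dimnames = list(c("s1", "s2"), "mX")),
                        c(mX = "NR_positive"))
  one$normalized <- TRUE
  m1 <- merge_module_factors(one)
  expect_null(m1$merged$MF_R)
  expect_equal(m1$merged$MF_NR, c(0.4, 0.6))
})

test_that("group tests match Welch oracles and adjustment is monotone", {
  v <- matrix(c(10, 11, 12, 0, 1, 2,
                5, 6, 7, 5, 6, 7), 6, 2,
              dimnames = list(paste0("s", 1:6), c("strong", "null")))
  mf <- mf_from_values(v, c(strong = "R_positive", null = "R_positive"))
  ph <- phenotype_table(setNames(c(rep("R", 3), rep("NR", 3)), paste0("s", 1:6)))
  tt <- mf_group_test(mf, ph)
  expect_lt(tt$p[tt$feature == "strong"], 0.001)
  expect_equal(tt$p[tt$feature == "strong"],
               t.test(c(10, 11, 12), c(0, 1, 2))$p.value, tolerance = 1e-12)
  # identical group values: no difference, p = 1
  expect_equal(tt$p[tt$feature == "null"], 1)
  expect_true(all(tt$p_adj >= tt$p - 1e-15))
  # hand-evaluated Holm-Sidak on the two p-values
  p <- sort(tt$p)
  expect_equal(sort(tt$p_adj),
               pmin(cummax(c(1 - (1 - p[1])^2, 1 - (1 - p[2])^1)), 1),
               tolerance = 1e-12)
  expect_identical(tt$stars[tt$feature == "null"], "ns")
})

test_that("forward selection recovers the planted signal modules with balance", {
  mods9 <- c(lapply(1:3, function(i) list(size = 40, delta = 0.8)),
             lapply(1:2, function(i) list(size = 40, delta = -0.8)),
             lapply(1:4, function(i) list(size = 40, delta = 0)))
  co <- generate_cohort(synthetic_config(modules = mods9, n_background = 200,
                                         seed = 7))
  e <- lognormalize(filter_genes(co$expr))
  st <- pick_soft_threshold(e)
  dm <- detect_modules(tom_matrix(adjacency_matrix(e, st$power)), expr = e)
  eig <- module_eigengenes(e, dm)
  ms <- module_trait_stats(eig, co$pheno)
  gs <- gene_trait_stats(e, co$pheno)
  sets <- suppressWarnings(select_module_genes(dm, gs, ms))
  mf <- minmax_normalize(compute_module_factors(e, sets))
  sel <- select_feature_modules(mf, co$pheno, ms, seed = 1)

  expect_length(sel$selected, 5)
  expect_equal(unname(sel$direction_counts[c("R_positive", "NR_positive")]),
               c(3L, 2L), ignore_attr = TRUE)
  truth <- co$truth$gene_module[rownames(e)]
  planted <- vapply(sel$selected, function(m)
    names(which.max(table(truth[unclass(dm) == m]))), character(1))
  expect_setequal(planted, c("1", "2", "3", "4", "5"))   # never a null module

  # immediate-stop rule: epsilon = Inf keeps one module per direction
  sel2 <- select_feature_modules(mf, co$pheno, ms, epsilon = Inf, seed = 1)
  expect_length(sel2$selected, 2)
  expect_setequal(unname(attr(sets, "direction")[sel2$selected]),
                  c("R_positive", "NR_positive"))

  # trace contract
  expect_true(all(sel$trace$cv_auc >= 0 & sel$trace$cv_auc <= 1))
  expect_equal(nrow(sel$trace), length(unique(sel$trace$module)))
})
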