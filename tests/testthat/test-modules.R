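block_tom <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  tom <- matrix(between, n, n)
  start <- 1
  for (s in sizes) {
    idx <- start:(start + s - 1)
    tom[idx, idx] <- within
    start <- start + s
  }
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  tom
}

test_that("perfectly separated blocks are detected exactly", {
  tom <- block_tom(c(40, 35))
  mods <- detect_modules(tom, network_params(min_module_size = 30))
  labs <- unclass(mods)
  expect_equal(sort(unique(labs)), c("module_1", "module_2"))
  expect_equal(sum(labs == "module_1"), 40)   # size-ranked labels
  expect_equal(sum(labs == "module_2"), 35)
  expect_false(any(labs == "unassigned"))
})

test_that("an identity-like TOM leaves every gene unassigned", {
  set.seed(4)
  n <- 60
  eps <- matrix(runif(n * n, 0, 1e-4), n, n)
  tom <- (eps + t(eps)) / 2
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  mods <- detect_modules(tom, network_params(min_module_size = 10))
  expect_true(all(unclass(mods) == "unassigned"))
})

test_that("fewer genes than min_module_size warns and unassigns everything", {
  tom <- block_tom(10)
  expect_warning(mods <- detect_modules(tom, network_params(min_module_size = 30)),
                 "unassigned")
  expect_true(all(unclass(mods) == "unassigned"))
})

test_that("planted modules are recovered from a synthetic cohort", {
  co <- generate_cohort(synthetic_config(
    n_samples = 60,
    modules = list(list(size = 60, delta = 0.8), list(size = 60, delta = 0.8),
                   list(size = 60, delta = 0.8)),
    n_background = 300, seed = 3))
  e <- lognormalize(filter_genes(co$expr))
  st <- pick_soft_threshold(e)
  mods <- detect_modules(tom_matrix(adjacency_matrix(e, st$power)), expr = e)
  truth <- co$truth$gene_module[rownames(e)]
  expect_gte(module_recovery_ari(unclass(mods), truth), 0.8)
})

test_that("eigengenes recover a rank-1 module profile up to the sign convention", {
  set.seed(8)
  profile <- rnorm(12)
  m <- matrix(rep(profile, each = 5), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  m <- m + matrix(rnorm(60, sd = 1e-8), 5, 12)
  e <- expression_matrix(m, "lognorm")
  mods <- structure(setNames(rep("module_1", 5), rownames(m)),
                    class = "module_assignment")
  eig <- module_eigengenes(e, mods)
  # equals the standardized common profile, orientation fixed positive
  expect_equal(unname(eig[, 1]), as.numeric(scale(profile)), tolerance = 1e-4)
  expect_equal(sd(eig[, 1]), 1, tolerance = 1e-12)

  # flipping all genes flips nothing observable after sign orientation
  eflip <- expression_matrix(-m + 10, "lognorm")
  eig2 <- module_eigengenes(eflip, mods)
  expect_gt(abs(cor(eig[, 1], eig2[, 1])), 0.999)
})

test_that("eigengene variance explained matches a full SVD", {
  e <- random_expr(9, 10, seed = 12)
  mods <- structure(setNames(rep(c("module_1", "module_2"), c(5, 4)), rownames(e)),
                    class = "module_assignment")
  eig <- module_eigengenes(e, mods)
  ve <- attr(eig, "var_explained")
  for (m in colnames(eig)) {
    xs <- scale(t(unclass(e)[names(unclass(mods))[unclass(mods) == m], ]))
    d <- svd(xs)$d
    expect_equal(ve[[m]], d[1]^2 / sum(d^2), tolerance = 1e-12)
  }
  expect_equal(unname(apply(eig, 2, sd)), rep(1, 2), tolerance = 1e-12)
})

test_that("module-trait correlations and p-values follow the t transform", {
  ph <- random_pheno(sprintf("s%02d", 1:12), n_r = 6, seed = 3)
  trait <- ph$trait
  eig <- cbind(m1 = as.numeric(scale(trait)),
               m2 = as.numeric(scale(residuals(lm(rnorm(12) ~ trait)))))
  rownames(eig) <- ph$sample_id
  ms <- module_trait_stats(eig, ph)
  expect_equal(ms$eigengene_cor[1], 1, tolerance = 1e-12)
  expect_equal(ms$direction[1], "R_positive")
  expect_lt(abs(ms$eigengene_cor[2]), 1e-12)

  set.seed(5)
  eig3 <- matrix(rnorm(36), 12, 3, dimnames = list(ph$sample_id, paste0("m", 1:3)))
  ms3 <- module_trait_stats(eig3, ph)
  for (i in 1:3) {
    r <- cor(eig3[, i], trait)
    tt <- r * sqrt((12 - 2) / (1 - r^2))
    expect_equal(ms3$p[i], 2 * pt(abs(tt), 10, lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("gene significance, p and BH-FDR match their definitions", {
  m <- matrix(c(2, 2, 1, 1, 5, 1, 4, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  ph <- phenotype_table(setNames(c("R", "R", "NR", "NR"), paste0("s", 1:4)))
  gs <- gene_trait_stats(expression_matrix(m, "lognorm"), ph)
  expect_equal(gs$gs[gs$gene_id == "gA"], 1, tolerance = 1e-12)

  # hand-evaluated BH: p = (0.01, 0.02, 0.03) with m = 3 -> all 0.03
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))

  e <- random_expr(20, 14, seed = 21)
  ph2 <- random_pheno(colnames(e), n_r = 7, seed = 2)
  gs2 <- gene_trait_stats(e, ph2)
  expect_equal(gs2$fdr, oracle_bh(gs2$p), tolerance = 1e-12)
  expect_true(all(gs2$fdr >= gs2$p - 1e-15))
  expect_equal(gs2$fdr, p.adjust(gs2$p, "BH"), tolerance = 1e-15)
})

test_that("GS signs recover the planted module directions", {
  co <- generate_cohort(synthetic_config(n_samples = 80, seed = 31))
  e <- lognormalize(filter_genes(co$expr))
  gs <- gene_trait_stats(e, co$pheno)
  truth <- co$truth
  for (m in names(truth$module_delta)) {
    genes <- intersect(names(truth$gene_module)[truth$gene_module == m], gs$gene_id)
    med <- median(gs$gs[match(genes, gs$gene_id)])
    if (truth$module_delta[[m]] > 0) expect_gt(med, 0) else expect_lt(med, 0)
  }
})

test_that("FDR control on a null cohort is far stricter than raw p", {
  res <- vapply(1:20, function(s) {
    co <- generate_cohort(synthetic_config(
      n_samples = 40, modules = list(list(size = 20, delta = 0)),
      n_background = 180, seed = 300 + s))
    gs <- gene_trait_stats(lognormalize(co$expr), co$pheno)
    c(fdr = mean(gs$fdr < 0.4), p = mean(gs$p < 0.4))
  }, numeric(2))
  expect_lt(mean(res["fdr", ]), 0.25 * mean(res["p", ]))
})
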