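#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by an adaptive branch cut and eigengene-based module merging.
#'
#' The cut is branch-adaptive rather than a single global height: among all
#' dendrogram nodes viable as modules — at least `min_module_size` genes,
#' tight (mean within-cluster TOM above a `deep_split`-controlled multiple
#' of the global off-diagonal mean), and formed by a genuinely co-expressed
#' merge (the joining similarity of the node's two halves exceeds the same
#' multiple, which stops a branch from accreting background genes past the
#' point where its module is complete) — an exact dynamic program over the
#' tree picks the disjoint set of nodes maximizing first the number of
#' modules and then the number of genes they cover. Each module is therefore cut at its own height, so a
#' loose module completing high in the tree cannot force two well-separated
#' modules to merge, and a branch slowly accreting background genes is
#' rejected in favor of the completed module inside it. The tightness rule
#' prevents a near-identity TOM from being reported as one giant module:
#' with no viable node, everything is "unassigned". Genes outside every
#' selected node are "unassigned". Finally, modules
#' whose eigengenes (computed from `expr` when supplied, else from the TOM
#' rows) correlate above `1 - merge_cut_height` are merged, and surviving
#' modules are renamed `module_1`, `module_2`, ... in decreasing size order
#' so labels are deterministic.
#'
#' @param tom topological overlap matrix from [tom_matrix()].
#' @param params a [network_params()].
#' @param expr optional lognorm [expression_matrix()] (same genes) used for
#'   eigengene-based merging; strongly recommended.
#' @return A `module_assignment`: named character vector gene -> label
#'   (`module_k` or `"unassigned"`), with a `dendro` attribute holding the
#'   hclust tree.
#' @export
detect_modules <- function(tom, params = network_params(), expr = NULL) {
  n <- nrow(tom)
  genes <- rownames(tom) %||% sprintf("G%05d", seq_len(n))
  if (n < params$min_module_size) {
    warning("fewer genes (", n, ") than min_module_size (",
            params$min_module_size, "); all genes unassigned", call. = FALSE)
    return(new_module_assignment(stats::setNames(rep("unassigned", n), genes), NULL))
  }
  diss <- 1 - tom
  dimnames(diss) <- list(genes, genes)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  off_mean <- (sum(tom) - n) / (n * (n - 1))

  # Per internal node: size, member leaves, and within-cluster TOM sum
  # (off-diagonal). Average linkage makes the merge height the mean cross
  # dissimilarity, so the cross TOM sum of a merge is |A||B|(1 - height) and
  # node statistics accumulate in one pass over the merge table.
  nm <- nrow(hc$merge)
  size <- s_within <- numeric(nm)
  leaves <- vector("list", nm)
  for (i in seq_len(nm)) {
    ch <- hc$merge[i, ]
    a <- if (ch[1] < 0) list(1, 0, -ch[1]) else list(size[ch[1]], s_within[ch[1]], leaves[[ch[1]]])
    b <- if (ch[2] < 0) list(1, 0, -ch[2]) else list(size[ch[2]], s_within[ch[2]], leaves[[ch[2]]])
    size[i] <- a[[1]] + b[[1]]
    s_within[i] <- a[[2]] + b[[2]] + 2 * a[[1]] * b[[1]] * (1 - hc$height[i])
    leaves[[i]] <- c(a[[3]], b[[3]])
  }
  # A viable module node must be (i) large enough, (ii) tight — mean within
  # TOM above a multiple of the global off-diagonal mean — and (iii) formed
  # by a genuinely co-expressed merge: the TOM similarity at which its two
  # halves join (1 - merge height under average linkage) must exceed the
  # same multiple of the global mean. (iii) is what stops background
  # accretion: a branch that keeps swallowing background genes after its
  # module is complete forms those later nodes at noise-floor similarity,
  # so only the completed module inside it remains viable. The multiple is
  # deep_split-controlled: higher values are more permissive and admit
  # finer, weaker modules.
  cohesion <- s_within / (size * (size - 1))
  factor_min <- c(4, 3, 2, 1.5, 1.2)[params$deep_split + 1]
  tight <- size >= params$min_module_size &
    cohesion > factor_min * off_mean &
    (1 - hc$height) > factor_min * off_mean

  labels <- stats::setNames(rep("unassigned", n), genes)
  if (any(tight)) {
    # Bottom-up DP: for every node, the best disjoint set of tight nodes in
    # its subtree — maximize module count, then gene coverage; on a full tie
    # deep_split >= 3 prefers splitting the node, lower values keep it whole.
    count <- cover <- numeric(nm)
    sel <- vector("list", nm)
    for (i in seq_len(nm)) {
      ch <- hc$merge[i, ]
      val <- function(j) if (j < 0) list(0, 0, integer(0)) else list(count[j], cover[j], sel[[j]])
      a <- val(ch[1]); b <- val(ch[2])
      split_count <- a[[1]] + b[[1]]; split_cover <- a[[2]] + b[[2]]
      take <- tight[i] &&
        (1 > split_count || (1 == split_count &&
           (size[i] > split_cover || (size[i] == split_cover && params$deep_split < 3))))
      if (take) {
        count[i] <- 1; cover[i] <- size[i]; sel[[i]] <- i
      } else {
        count[i] <- split_count; cover[i] <- split_cover; sel[[i]] <- c(a[[3]], b[[3]])
      }
    }
    chosen <- sel[[nm]]
    for (k in seq_along(chosen))
      labels[leaves[[chosen[k]]]] <- paste0("raw_", k)
    if (length(chosen) && !is.null(expr))
      labels <- kme_refine(labels, expr, params)
    if (any(labels != "unassigned"))
      labels <- merge_close_modules(labels, tom, expr, params$merge_cut_height)
  }
  new_module_assignment(relabel_by_size(labels), hc)
}

#' @keywords internal
#' @noRd
new_module_assignment <- function(labels, dendro) {
  structure(labels, dendro = dendro, class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- sort(table(unclass(x)), decreasing = TRUE)
  cat("module_assignment:", length(x), "genes,",
      sum(names(tab) != "unassigned"), "modules\n")
  print(tab)
  invisible(x)
}

# Module-membership (kME) refinement: compute the eigengene of every raw
# module, then reassign each gene to the module whose eigengene it
# correlates with most strongly in absolute value, provided |kME| reaches
# kme_min; all other genes become unassigned. This recovers module genes the
# tree cut stranded and strips background genes that hitch-hiked into a
# branch through chance correlation, whose |kME| is near its null level.
# Modules falling below min_module_size afterwards dissolve.
#' @keywords internal
#' @noRd
kme_refine <- function(labels, expr, params) {
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) return(labels)
  src <- t(unclass(expr))
  eig <- sapply(mods, function(m) first_pc(src[, names(labels)[labels == m], drop = FALSE]))
  kme <- stats::cor(src, eig)          # genes x modules
  best <- max.col(abs(kme), ties.method = "first")
  ok <- abs(kme)[cbind(seq_along(best), best)] >= params$kme_min
  out <- stats::setNames(ifelse(ok, mods[best], "unassigned"), rownames(kme))
  out <- out[names(labels)]
  for (m in mods) if (sum(out == m) < params$min_module_size) out[out == m] <- "unassigned"
  out
}

# Iteratively merge modules whose eigengenes correlate above 1 - cut_height.
# Falls back to TOM-profile eigengenes when expression is not supplied.
#' @keywords internal
#' @noRd
merge_close_modules <- function(labels, tom, expr, cut_height) {
  profile_source <- function() {
    if (!is.null(expr)) t(unclass(expr)) else tom
  }
  src <- profile_source()
  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2) return(labels)
    eig <- sapply(mods, function(m) {
      cols <- names(labels)[labels == m]
      first_pc(src[, cols, drop = FALSE])
    })
    cc <- stats::cor(eig)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[top[1], top[2]] <= 1 - cut_height) return(labels)
    labels[labels == mods[top[2]]] <- mods[top[1]]
  }
}

# First principal component of a (observations x variables) matrix after
# standardizing columns; returned with unit variance, sign-oriented so it
# correlates positively with the mean standardized profile.
#' @keywords internal
#' @noRd
first_pc <- function(x) {
  xs <- scale(x)
  xs[is.na(xs)] <- 0
  sv <- svd(xs, nu = 1, nv = 0)
  pc <- sv$u[, 1]
  if (stats::sd(pc) == 0) mf_stop("zero-variance module; cannot form an eigengene")
  pc <- pc / stats::sd(pc)
  ref <- rowMeans(xs)
  if (sum(pc * ref) < 0) pc <- -pc
  pc
}

#' @keywords internal
#' @noRd
relabel_by_size <- function(labels) {
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), numeric(1))
  # size-ranked; ties broken by first gene position for determinism
  firsts <- vapply(mods, function(m) which(labels == m)[1], numeric(1))
  ord <- order(-sizes, firsts)
  new <- stats::setNames(paste0("module_", seq_along(mods)), mods[ord])
  out <- labels
  for (m in mods) out[labels == m] <- new[[m]]
  out
}

#' Module eigengenes
#'
#' One eigengene per module: the first principal component of the module's
#' standardized expression across samples, scaled to unit variance and
#' sign-oriented so it correlates positively with the module's mean
#' standardized expression. The "unassigned" group is treated as a module in
#' its own right, because downstream feature construction deliberately keeps
#' it as a candidate.
#'
#' @param expr lognorm-scale [expression_matrix()].
#' @param modules a `module_assignment` covering the matrix genes.
#' @return samples x modules numeric matrix with a `var_explained` attribute
#'   (fraction of module variance captured by each eigengene).
#' @export
module_eigengenes <- function(expr, modules) {
  assert_scale(expr, "lognorm", "module_eigengenes")
  labs <- unclass(modules)[rownames(expr)]
  if (anyNA(labs)) mf_stop("module assignment does not cover all matrix genes")
  mods <- unique(labs)
  mods <- c(setdiff(sort(mods), "unassigned"),
            intersect("unassigned", mods))
  keep <- mods[vapply(mods, function(m) sum(labs == m) >= 2, logical(1))]
  if (!length(keep)) mf_stop("no module with >= 2 genes")
  ve <- numeric(length(keep))
  eig <- matrix(NA_real_, ncol(expr), length(keep),
                dimnames = list(colnames(expr), keep))
  for (i in seq_along(keep)) {
    xs <- scale(t(unclass(expr)[labs == keep[i], , drop = FALSE]))
    if (anyNA(xs)) mf_stop("zero-variance gene inside module ", keep[i])
    sv <- svd(xs, nu = 1, nv = 0)
    pc <- sv$u[, 1]
    pc <- pc / stats::sd(pc)
    if (sum(pc * rowMeans(xs)) < 0) pc <- -pc
    eig[, i] <- pc
    ve[i] <- sv$d[1]^2 / sum(svd(xs, nu = 0, nv = 0)$d^2)
  }
  attr(eig, "var_explained") <- stats::setNames(ve, keep)
  eig
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with the binary trait code
#' (R = 1, NR = 0), two-sided p from the t transform with n - 2 df, and the
#' implied direction: `R_positive` when the eigengene rises in rejectors,
#' `NR_positive` otherwise.
#'
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param pheno a [phenotype_table()] covering the samples.
#' @return Data frame with columns `module`, `eigengene_cor`, `p`,
#'   `direction`.
#' @export
module_trait_stats <- function(eigengenes, pheno) {
  ph <- align_phenotype(pheno, rownames(eigengenes))
  n <- nrow(eigengenes)
  r <- as.numeric(stats::cor(eigengenes, ph$trait))
  data.frame(module = colnames(eigengenes),
             eigengene_cor = r,
             p = cor_pvalue(r, n),
             direction = ifelse(r >= 0, "R_positive", "NR_positive"),
             stringsAsFactors = FALSE)
}

#' Gene-trait significance (GS)
#'
#' Per-gene Pearson correlation with the trait code (R = 1, NR = 0) — the GS
#' weight used in module factor construction — with its two-sided p-value and
#' Benjamini-Hochberg FDR. By default the FDR adjustment is transcriptome-wide
#' (across all genes in the matrix); set `modules` to adjust within each
#' module separately.
#'
#' @param expr lognorm-scale [expression_matrix()].
#' @param pheno a [phenotype_table()].
#' @param modules optional `module_assignment`; when given, BH is applied per
#'   module instead of across all genes.
#' @return Data frame with columns `gene_id`, `gs`, `p`, `fdr`.
#' @export
gene_trait_stats <- function(expr, pheno, modules = NULL) {
  assert_scale(expr, "lognorm", "gene_trait_stats")
  ph <- align_phenotype(pheno, colnames(expr))
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    mf_stop("zero-variance gene(s), GS undefined: ",
            paste(utils::head(rownames(expr)[v == 0], 10), collapse = ", "))
  gs <- as.numeric(stats::cor(t(unclass(expr)), ph$trait))
  p <- cor_pvalue(gs, ncol(expr))
  if (is.null(modules)) {
    fdr <- stats::p.adjust(p, method = "BH")
  } else {
    labs <- unclass(modules)[rownames(expr)]
    fdr <- stats::ave(p, labs, FUN = function(z) stats::p.adjust(z, method = "BH"))
  }
  data.frame(gene_id = rownames(expr), gs = gs, p = p, fdr = fdr,
             stringsAsFactors = FALSE)
}
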