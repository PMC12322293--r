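#' Network construction parameters
#'
#' @param power soft-threshold exponent beta; `NULL` means pick it with
#'   [pick_soft_threshold()].
#' @param candidate_powers powers scanned during selection (default 1..20).
#' @param fit_target scale-free topology fit index the selected power must
#'   reach (default 0.82).
#' @param min_module_size smallest gene count a cluster needs to become a
#'   module (default 30).
#' @param merge_cut_height modules whose eigengenes correlate above
#'   `1 - merge_cut_height` are merged (default 0.25).
#' @param deep_split 0..4; higher values admit weaker, finer modules in the
#'   branch cut (default 2).
#' @param kme_min minimum absolute module membership (correlation with the
#'   module eigengene) a gene needs to stay in a module during the
#'   kME refinement stage of [detect_modules()] (default 0.4).
#' @param network_type only `"unsigned"` (adjacency `|cor|^beta`) is
#'   implemented; `"signed_hybrid"` zeroes negative correlations first.
#' @return A `network_params` list.
#' @export
network_params <- function(power = NULL, candidate_powers = 1:20,
                           fit_target = 0.82, min_module_size = 30,
                           merge_cut_height = 0.25, deep_split = 2,
                           kme_min = 0.4,
                           network_type = c("unsigned", "signed_hybrid")) {
  network_type <- match.arg(network_type)
  stopifnot(all(candidate_powers >= 1), fit_target > 0, fit_target <= 1,
            min_module_size >= 1, merge_cut_height > 0, merge_cut_height < 1,
            deep_split %in% 0:4, kme_min >= 0, kme_min < 1)
  if (!is.null(power) && !(power %in% candidate_powers))
    mf_stop("power must be one of candidate_powers")
  structure(list(power = power, candidate_powers = as.integer(candidate_powers),
                 fit_target = fit_target, min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height, deep_split = as.integer(deep_split),
                 kme_min = kme_min, network_type = network_type),
            class = "network_params")
}

#' @keywords internal
#' @noRd
gene_correlation <- function(expr) {
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    mf_stop("zero-variance gene(s), filter before network construction: ",
            paste(utils::head(rownames(expr)[v == 0], 10), collapse = ", "))
  stats::cor(t(unclass(expr)))
}

#' @keywords internal
#' @noRd
cor_to_adjacency <- function(cmat, power, network_type = "unsigned") {
  a <- if (network_type == "signed_hybrid") pmax(cmat, 0) else abs(cmat)
  a <- a^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit index for one connectivity vector
#'
#' Bins connectivities into `n_bins` equal-count bins, estimates the density
#' in each bin as count / (n * bin width), and regresses log10(density) on
#' log10(mean connectivity). The index is -sign(slope) * R^2, so it is
#' positive only when frequency decays with connectivity, as a scale-free
#' degree distribution requires. Bins collapsed by ties are dropped.
#' @keywords internal
#' @noRd
scale_free_fit <- function(k, n_bins = 10) {
  n <- length(k)
  br <- stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1), names = FALSE)
  br <- unique(br)
  if (length(br) < 3) return(NA_real_)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = length(br) - 1)
  width <- diff(br)
  dens <- counts / (n * width)
  mean_k <- tapply(k, bin, mean)
  ok <- counts > 0 & dens > 0 & mean_k > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(dens[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Pick the soft-threshold power
#'
#' Scans candidate powers and returns the lowest one whose scale-free
#' topology fit index reaches `fit_target`. For each power the whole-network
#' connectivity is `k_i = sum_{j != i} |cor(x_i, x_j)|^beta`; the fit index is
#' the signed R^2 of the log-log regression of the binned connectivity
#' density on mean connectivity (10 equal-count bins).
#'
#' @param expr lognorm-scale [expression_matrix()] with >= 3 samples.
#' @param params a [network_params()].
#' @return List with `power` (selected beta), `fit_table` (data frame of
#'   power, fit index, mean and max connectivity), and `reached_target`
#'   (logical). When no candidate reaches the target the power maximizing
#'   the fit index is returned and a warning is issued.
#' @export
pick_soft_threshold <- function(expr, params = network_params()) {
  assert_scale(expr, "lognorm", "pick_soft_threshold")
  if (ncol(expr) < 3) mf_stop("need at least 3 samples to pick a soft threshold")
  cmat <- gene_correlation(expr)
  base <- if (params$network_type == "signed_hybrid") pmax(cmat, 0) else abs(cmat)
  diag(base) <- 0
  rows <- lapply(params$candidate_powers, function(beta) {
    k <- rowSums(base^beta)
    data.frame(power = beta, fit_index = scale_free_fit(k),
               mean_k = mean(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$fit_index) & tab$fit_index >= params$fit_target)
  if (length(hit)) {
    power <- tab$power[hit[1]]
    reached <- TRUE
  } else {
    power <- tab$power[which.max(tab$fit_index)]
    reached <- FALSE
    warning("no candidate power reached fit index ", params$fit_target,
            "; using power ", power, " (max fit ",
            signif(max(tab$fit_index, na.rm = TRUE), 3), ")", call. = FALSE)
  }
  list(power = power, fit_table = tab, reached_target = reached)
}

#' Unsigned weighted adjacency matrix
#'
#' `a_ij = |Pearson cor(x_i, x_j)|^power`, diagonal set to 1.
#'
#' @param expr lognorm-scale [expression_matrix()].
#' @param power soft-threshold exponent.
#' @param network_type `"unsigned"` or `"signed_hybrid"`.
#' @return Symmetric gene-by-gene matrix with entries in \[0, 1\].
#' @export
adjacency_matrix <- function(expr, power, network_type = "unsigned") {
  assert_scale(expr, "lognorm", "adjacency_matrix")
  cor_to_adjacency(gene_correlation(expr), power, network_type)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` counts shared neighbors and
#' `k_i = sum_{u != i} a_iu` is connectivity; `TOM_ii = 1`. High overlap means
#' two genes are both directly connected and share their neighborhoods;
#' `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj symmetric adjacency with entries in \[0, 1\], unit diagonal.
#' @return Symmetric matrix, entries in \[0, 1\], unit diagonal.
#' @export
tom_matrix <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) mf_stop("adjacency must be symmetric")
  if (any(adj < 0) || any(adj > 1 + 1e-12)) mf_stop("adjacency entries must lie in [0, 1]")
  a <- unclass(adj)
  diag(a) <- 0
  l <- a %*% a                       # l_ij = sum_u a_iu a_uj, u != i,j since diag 0
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  # numerical guard: theory bounds TOM by 1, arithmetic can spill by eps
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  (tom + t(tom)) / 2
}
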