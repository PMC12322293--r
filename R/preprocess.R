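#' Filter low-signal genes
#'
#' Removes genes whose total raw expression falls below `min_total` (the
#' "FPKM sum" filter) or that are detected (value > 0) in too small a
#' fraction of samples. Both comparisons are inclusive: a gene with row sum
#' exactly `min_total`, or detection fraction exactly `min_fraction`, is
#' retained. Gene order and the sample set are unchanged.
#'
#' @param expr raw-scale [expression_matrix()].
#' @param min_total minimum row sum (default 50, the FPKM-sum rule).
#' @param min_fraction minimum fraction of samples with a positive value
#'   (default 0.02).
#' @return The filtered [expression_matrix()], still raw scale.
#' @examples
#' m <- matrix(c(20, 20, 20, 20, 49, 0, 0, 0), 2, 4, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' filter_genes(expression_matrix(m))  # g2 drops: row sum 49 < 50
#' @export
filter_genes <- function(expr, min_total = 50, min_fraction = 0.02) {
  assert_scale(expr, "raw", "filter_genes")
  keep <- rowSums(expr) >= min_total &
    rowMeans(expr > 0) >= min_fraction
  if (!any(keep))
    mf_stop("all genes removed by filtering; relax min_total (", min_total,
            ") and/or min_fraction (", min_fraction, ")")
  expr[keep, , drop = FALSE]
}

#' Log-normalize expression
#'
#' Per-sample library-size scaling followed by a log transform:
#' `out[g, s] = ln(x[g, s] / colsum_s * scale_factor + 1)`. This is the
#' standard single-cell-style normalization applied here to bulk FPKM
#' matrices; column re-scaling of already depth-normalized FPKM is debatable,
#' so `rescale = FALSE` skips the library-size division and applies
#' `ln(x + 1)` only.
#'
#' @param expr raw-scale [expression_matrix()].
#' @param scale_factor target library size after re-scaling (default 1e4).
#' @param rescale divide by column sums first (default TRUE).
#' @return A lognorm-scale [expression_matrix()].
#' @export
lognormalize <- function(expr, scale_factor = 1e4, rescale = TRUE) {
  assert_scale(expr, "raw", "lognormalize")
  vals <- unclass(expr)
  if (rescale) {
    cs <- colSums(vals)
    if (any(cs <= 0))
      mf_stop("zero column sum for sample(s): ",
              paste(colnames(expr)[cs <= 0], collapse = ", "))
    vals <- sweep(vals, 2, cs, "/") * scale_factor
  }
  expression_matrix(log1p(vals), "lognorm")
}
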