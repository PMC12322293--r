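#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric gene-by-sample matrix that tracks
#' whether values are on the raw (FPKM-like, non-negative) scale or have been
#' log-normalized. All pipeline stages check the scale flag so that, e.g.,
#' filtering thresholds stated on FPKM sums cannot accidentally be applied to
#' log values.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Dimnames
#'   are required (gene IDs and sample IDs) and must be unique.
#' @param scale either `"raw"` or `"lognorm"`.
#' @return An `expression_matrix`: the matrix with a `scale` attribute.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, scale = c("raw", "lognorm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    mf_stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    mf_stop("'values' must have gene IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(values)))
    mf_stop("duplicate gene IDs: ",
            paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    mf_stop("duplicate sample IDs: ",
            paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) mf_stop("expression matrix contains missing values")
  if (scale == "raw" && any(values < 0))
    mf_stop("raw-scale expression must be non-negative")
  structure(values, scale = scale, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (scale: %s)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' @keywords internal
#' @noRd
expr_scale <- function(x) attr(x, "scale") %||% "raw"

#' @keywords internal
#' @noRd
assert_scale <- function(x, scale, what) {
  if (!identical(expr_scale(x), scale))
    mf_stop(what, " requires ", scale, "-scale expression (got '", expr_scale(x), "')")
  invisible(x)
}

# Subsetting keeps ordinary matrix semantics; the class and scale flag are
# preserved whenever the result is still a matrix.
#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("expression_matrix", "matrix", "array"))
  out
}

#' Phenotype table: binary rejection labels
#'
#' Maps sample IDs to rejector ("R") / non-rejector ("NR") status and carries
#' the numeric trait code used for all correlations (R = 1, NR = 0).
#'
#' @param labels named character vector (names = sample IDs) with values
#'   `"R"` or `"NR"`.
#' @return A `phenotype_table` data frame with columns `sample_id`, `label`,
#'   `trait` (1 for R, 0 for NR).
#' @export
phenotype_table <- function(labels) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    mf_stop("'labels' must be named by unique sample IDs")
  ids <- names(labels)
  labels <- stats::setNames(as.character(labels), ids)
  bad <- setdiff(unique(labels), c("R", "NR"))
  if (length(bad))
    mf_stop("labels must be 'R' or 'NR'; found: ", paste(bad, collapse = ", "))
  structure(
    data.frame(sample_id = names(labels), label = unname(labels),
               trait = as.numeric(labels == "R"), stringsAsFactors = FALSE),
    class = c("phenotype_table", "data.frame"))
}

#' @keywords internal
#' @noRd
align_phenotype <- function(pheno, sample_ids, require_both = TRUE) {
  idx <- match(sample_ids, pheno$sample_id)
  if (anyNA(idx))
    mf_stop("phenotype table is missing samples: ",
            paste(sample_ids[is.na(idx)], collapse = ", "))
  out <- pheno[idx, , drop = FALSE]
  if (require_both && length(unique(out$label)) < 2)
    mf_stop("both classes (R and NR) must be present among the matrix samples")
  out
}
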