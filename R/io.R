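# Plain-text I/O for the pipeline's standard formats: gene-by-sample TSV/CSV,
# MatrixMarket triplets with gene/sample sidecar files, and 2-column
# phenotype tables.

#' Read a gene-by-sample expression matrix
#'
#' Delimited text (TSV/CSV, genes in rows, first column = gene IDs, header =
#' sample IDs) or MatrixMarket coordinate format. For `.mtx` files the gene
#' and sample IDs are read from `genes.tsv` / `samples.tsv` sidecars in the
#' same directory (override with `genes_file` / `samples_file`).
#'
#' @param path file path; format chosen by extension (`.mtx` vs other).
#' @param scale scale flag to attach, `"raw"` (default) or `"lognorm"`.
#' @param genes_file,samples_file optional sidecar paths for MTX input.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = "raw",
                            genes_file = NULL, samples_file = NULL) {
  if (!file.exists(path)) mf_stop("expression file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    values <- read_mtx_dense(path)
    genes_file <- genes_file %||% file.path(dirname(path), "genes.tsv")
    samples_file <- samples_file %||% file.path(dirname(path), "samples.tsv")
    if (!file.exists(genes_file)) mf_stop("MTX gene sidecar not found: ", genes_file)
    if (!file.exists(samples_file)) mf_stop("MTX sample sidecar not found: ", samples_file)
    rownames(values) <- readLines(genes_file)
    colnames(values) <- readLines(samples_file)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    values <- as.matrix(df[, -1, drop = FALSE])
    rownames(values) <- as.character(df[[1]])
    storage.mode(values) <- "double"
  }
  expression_matrix(values, scale)
}

# Minimal MatrixMarket coordinate reader (real/integer, general symmetry).
# Only the subset of the format the pipeline emits/consumes is supported.
#' @keywords internal
#' @noRd
read_mtx_dense <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate", header))
    mf_stop("unsupported MatrixMarket header in ", path)
  body <- lines[!startsWith(lines, "%")]
  dims <- scan(text = body[1], quiet = TRUE)
  out <- matrix(0, dims[1], dims[2])
  if (dims[3] > 0) {
    trip <- matrix(scan(text = body[-1], quiet = TRUE), ncol = 3, byrow = TRUE)
    out[cbind(trip[, 1], trip[, 2])] <- trip[, 3]
  }
  out
}

#' Write an expression matrix as delimited text or MatrixMarket
#'
#' @param expr an [expression_matrix()].
#' @param path output path; `.mtx` writes coordinate format plus `genes.tsv`
#'   and `samples.tsv` sidecars, `.csv` comma-separated, anything else TSV.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    nz <- which(expr != 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 sprintf("%d %d %d", nrow(expr), ncol(expr), nrow(nz))), con)
    if (nrow(nz))
      writeLines(sprintf("%d %d %.10g", nz[, 1], nz[, 2], expr[nz]), con)
    writeLines(rownames(expr), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(expr), file.path(dirname(path), "samples.tsv"))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- data.frame(gene_id = rownames(expr), as.data.frame(unclass(expr)[, , drop = FALSE]),
                     check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a 2-column phenotype table (sample_id, label)
#'
#' @param path TSV/CSV with columns `sample_id` and `label` (values R/NR);
#'   a header row is required.
#' @return A [phenotype_table()].
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) mf_stop("phenotype file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df)))
    mf_stop("phenotype file needs 'sample_id' and 'label' columns: ", path)
  phenotype_table(stats::setNames(df$label, df$sample_id))
}

#' Write a phenotype table as 2-column TSV
#' @param pheno a [phenotype_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.table(pheno[, c("sample_id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
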