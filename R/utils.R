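`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
mf_stop <- function(..., call. = FALSE) stop(..., call. = call.)

#' Two-sided p-value for a Pearson correlation
#'
#' Classic t transform: t = r * sqrt((n - 2) / (1 - r^2)) with n - 2 df.
#' Correlations of +/-1 map to p = 0.
#' @keywords internal
#' @noRd
cor_pvalue <- function(r, n) {
  if (n < 3) return(rep(NA_real_, length(r)))
  r <- pmin(pmax(r, -1), 1)
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  tt <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak: for the i-th smallest p of m, adj = 1 - (1 - p)^(m - i + 1),
#' with enforced monotonicity and capping at 1. This is the "multiple unpaired
#' t-tests" adjustment convention of common graphing software.
#' @keywords internal
#' @noRd
p_adjust_holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Significance stars at the conventional 0.05/0.01/0.001/0.0001 levels
#' @keywords internal
#' @noRd
p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("")
    if (x < 1e-4) "****" else if (x < 1e-3) "***" else if (x < 0.01) "**" else if (x < 0.05) "*" else "ns"
  }, character(1))
}

#' Deterministic sub-seed derivation, kept within 32-bit integer range
#' @keywords internal
#' @noRd
derive_seed <- function(seed0, offset) {
  (as.integer(seed0) %% 1000000L) * 1000L + (as.integer(offset) %% 1000L)
}
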