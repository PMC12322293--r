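# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, direct formulas) so they cannot share a
# code path with the implementation they check.

random_expr <- function(n_genes, n_samples, seed, scale = "lognorm") {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_samples, mean = 3)), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(m, scale)
}

random_pheno <- function(sample_ids, n_r, seed) {
  set.seed(seed)
  lab <- sample(c(rep("R", n_r), rep("NR", length(sample_ids) - n_r)))
  phenotype_table(setNames(lab, sample_ids))
}

# element-wise Pearson correlation via explicit loops
oracle_cor <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  as.numeric(num / sqrt(dx * dy))
}

oracle_adjacency <- function(values, power) {
  n <- nrow(values)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a[i, j] <- if (i == j) 1 else abs(oracle_cor(values[i, ], values[j, ]))^power
  }
  a
}

oracle_tom <- function(a) {
  n <- nrow(a)
  tom <- matrix(1, n, n)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# BH as the min over tails of p * m / rank
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  out <- numeric(m)
  for (r in seq_len(m)) {
    i <- o[r]
    tails <- sapply(r:m, function(rr) p[o[rr]] * m / rr)
    out[i] <- min(1, min(tails))
  }
  out
}

# AUC by enumerating all (R, NR) pairs; ties count 1/2
oracle_auc <- function(scores, y01) {
  pos <- which(y01 == 1); neg <- which(y01 == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# adjusted Rand index over genes assigned to detected modules
module_recovery_ari <- function(detected, truth) {
  keep <- detected != "unassigned"
  mclust::adjustedRandIndex(detected[keep], truth[keep])
}
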