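# Independent oracles used to check the package's implementations.

# 1-D optimal transport by exact quantile pairing: both empirical quantile
# functions are piecewise constant with breakpoints at i/na and j/nb, so
# integral |Qa - Qb| dp is summed interval by interval. Independent of the
# CDF-integration route used by emd_score().
oracle_emd <- function(a, b) {
  na <- length(a); nb <- length(b)
  breaks <- sort(unique(c(0, seq_len(na) / na, seq_len(nb) / nb)))
  widths <- diff(breaks)
  mids <- breaks[-length(breaks)] + widths / 2
  qa <- sort(a)[ceiling(mids * na)]
  qb <- sort(b)[ceiling(mids * nb)]
  sum(abs(qa - qb) * widths)
}

# Dense left-eigendecomposition of I - B^{-1} V V' ; returns the unit-norm
# absolute eigenvector for the smallest-magnitude eigenvalue.
oracle_lambda <- function(V, guard = 1e-12) {
  V <- as.matrix(V)
  S <- V %*% t(V)
  deg <- rowSums(S)
  deg[abs(deg) < guard] <- ifelse(deg[abs(deg) < guard] == 0, guard,
                                  sign(deg[abs(deg) < guard]) * guard)
  A <- diag(nrow(V)) - S / deg
  eig <- eigen(t(A))
  mu <- Re(eig$vectors[, order(Mod(eig$values))[1]])
  lam <- abs(mu)
  lam / sqrt(sum(lam^2))
}

# Adjusted Rand index by explicit O(m^2) pair counting.
oracle_ari <- function(la, lb) {
  m <- length(la)
  ss <- sd_ <- ds <- dd <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      sa <- la[i] == la[j]
      sb <- lb[i] == lb[j]
      if (sa && sb) ss <- ss + 1
      else if (sa && !sb) sd_ <- sd_ + 1
      else if (!sa && sb) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  denom <- (ss + sd_) * (sd_ + dd) + (ss + ds) * (ds + dd)
  if (denom == 0) return(as.numeric(sd_ + ds == 0))
  2 * (ss * dd - sd_ * ds) / denom
}

# Tiny deterministic expression matrix for I/O and filter tests.
tiny_matrix <- function(m = 4, n = 5, seed = 42) {
  set.seed(seed)
  vals <- matrix(round(runif(m * n, 0, 5), 3), m, n)
  expression_matrix(vals,
                    gene_names = paste0("g", seq_len(n)),
                    cell_ids = paste0("c", seq_len(m)))
}

# Two well-separated Gaussian blobs for k-selection tests (separation
# `sep` in units of the within-blob standard deviation).
make_blobs <- function(n_per = 50, dims = 5, sep = 10, seed = 1) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per * dims), n_per, dims)
  x2 <- matrix(rnorm(n_per * dims, mean = sep / sqrt(dims)), n_per, dims)
  rbind(x1, x2)
}
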