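# Shared test utilities.  Oracles here are built directly from the model
# formulas (per-site matrices + base kronecker), independently of the
# package's entrywise transition-probability code path.

# Per-site error matrix, written out directly.
oracle_site_matrix <- function(eps, eta_s) {
  matrix(c(1 - eps - eta_s + 2 * eps * eta_s, eta_s,
           eps + eta_s - 2 * eps * eta_s,     1 - eta_s), 2, 2)
}

# Dense 2^n x 2^n misclassification matrix via base kronecker().
oracle_dense_M <- function(eps, eta, n) {
  eta <- rep(eta, length.out = n)
  Reduce(kronecker, lapply(eta, function(h) oracle_site_matrix(eps, h)))
}

# All patterns of length n in index order, via strtoi-free enumeration.
oracle_patterns <- function(n) {
  grid <- do.call(expand.grid, rep(list(c("0", "1")), n))
  pats <- do.call(paste0, grid[rev(seq_len(n))])
  sort(pats, method = "radix")
}

# Log-likelihood through the dense oracle matrix.  theta indexed over all
# 2^n patterns in index order; y a named count vector.
oracle_loglik <- function(theta_full, y, eps, eta, n) {
  M <- oracle_dense_M(eps, eta, n)
  pats <- oracle_patterns(n)
  phi <- drop(theta_full %*% M)
  idx <- match(names(y), pats)
  if (any(phi[idx] == 0)) return(-Inf)
  sum(y * log(phi[idx]))
}

# Random count table over a random subset of patterns.
random_counts <- function(n, n_patterns, N) {
  pats <- sample(oracle_patterns(n), n_patterns)
  y <- drop(stats::rmultinom(1, N, rep(1 / n_patterns, n_patterns)))
  keep <- y > 0
  pattern_counts(pats[keep], y[keep])
}

# Rows of iid Dirichlet(1) points on the (m-1)-simplex.
runif_simplex <- function(k, m) {
  g <- matrix(stats::rexp(k * m), k, m)
  g / rowSums(g)
}
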