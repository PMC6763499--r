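# Independent oracle implementations used across the suite.  These stay
# deliberately naive (dense double loops, exhaustive pair counting) so that
# they share no code path with the package.

# Dense O(N^2) Geary's C: builds the full weight matrix from the graph and
# evaluates the double sum directly.
geary_oracle <- function(values, graph) {
  n <- length(values)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, graph$index[i, ]] <- graph$weight[i, ]
  }
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * (values[i] - values[j])^2
    }
  }
  (n - 1) * num / (2 * sum(W) * sum((values - mean(values))^2))
}

# Exhaustive AUROC: wins + half ties over all n1*n2 pairs.
auroc_oracle <- function(x, y) {
  wins <- 0
  for (xi in x) {
    for (yj in y) {
      wins <- wins + (xi > yj) + 0.5 * (xi == yj)
    }
  }
  wins / (length(x) * length(y))
}

# Textbook Benjamini-Hochberg step-up: q_i = min over j >= i of p_(j)*m/j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- min(prev, 1)
  }
  q
}

# Random expression fixture: lognormal values with gene-level mean
# structure (as real data has), named dims.
random_expr <- function(n_genes, n_cells, seed = 1) {
  withr::with_seed(seed, {
    mu <- rnorm(n_genes)
    m <- matrix(exp(mu + rnorm(n_genes * n_cells)), n_genes, n_cells,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%03d", seq_len(n_cells))))
    m
  })
}

# 1-D chain layout: cells spaced on a line so neighbourhoods follow the
# ordering; useful for planting monotone signals.
chain_latent <- function(n) {
  m <- matrix(seq_len(n), ncol = 1)
  rownames(m) <- sprintf("c%03d", seq_len(n))
  m
}

# Two well-separated Gaussian blobs in 2-D.
blob_latent <- function(n_per_blob, sep = 50, seed = 1) {
  withr::with_seed(seed, {
    m <- rbind(
      matrix(rnorm(2 * n_per_blob), ncol = 2),
      matrix(rnorm(2 * n_per_blob), ncol = 2) + sep
    )
    rownames(m) <- sprintf("c%03d", seq_len(2 * n_per_blob))
    m
  })
}
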