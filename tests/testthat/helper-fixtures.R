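# Shared fixtures: all built in code at test time.

# Small random count matrix with a guaranteed nonzero entry per row.
random_counts <- function(n = 10, m = 8, lambda = 2, seed = 1,
                          modality = "rna") {
  set.seed(seed)
  x <- matrix(rpois(n * m, lambda), n, m)
  empty <- rowSums(x) == 0
  x[empty, 1] <- 1
  counts_matrix(x, modality = modality)
}

# Random small Poisson NMF fit with positive entries.
random_nmf_fit <- function(n, m, K, seed = 1) {
  set.seed(seed)
  topicDE:::new_poisson_nmf_fit(W = matrix(rgamma(m * K, 2, 2), m, K),
                                H = matrix(rgamma(n * K, 2, 2), n, K))
}

# Dense brute-force Poisson log-likelihood (independent of the package's
# sparse computation).
dense_poisson_loglik <- function(x, H, W) {
  lam <- H %*% t(W)
  xm <- as.matrix(x$values)
  term <- ifelse(xm > 0, xm * log(lam), 0)
  sum(term) - sum(lam)
}

# Hard two-group membership matrix: first n1 cells in topic 1.
hard_two_groups <- function(n1, n2) {
  rbind(matrix(c(1, 0), n1, 2, byrow = TRUE),
        matrix(c(0, 1), n2, 2, byrow = TRUE))
}

# Monte Carlo standard error by batch means (for autocorrelated chains).
batch_se <- function(v, nbatch = 50) {
  nb <- floor(length(v) / nbatch)
  bm <- colMeans(matrix(v[seq_len(nb * nbatch)], nb, nbatch))
  sd(bm) / sqrt(nbatch)
}
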