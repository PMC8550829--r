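# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (scalar loops, direct eigendecompositions, hand tallies)
# and never call the vectorized code paths they verify.

# two Gaussian blobs, returned as a list(x, y) with labels 0/1
make_blobs <- function(n_per = 20, d = 2, sep = 4, seed = 1) {
  with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), ncol = d),
               matrix(rnorm(n_per * d, mean = sep / sqrt(d)), ncol = d))
    list(x = x, y = rep(0:1, each = n_per))
  })
}

# scalar-loop hybrid Gram oracle built from the single-kernel scalar calls
gram_oracle <- function(Xa, Xb, w, params) {
  K <- matrix(NA_real_, nrow(Xa), nrow(Xb))
  for (i in seq_len(nrow(Xa))) {
    for (j in seq_len(nrow(Xb))) {
      u <- Xa[i, ]; v <- Xb[j, ]
      lin <- kernel_linear(u, v)
      rbf <- kernel_rbf(u, v, params$rbf_gamma)
      pol <- kernel_polynomial(u, v, params)
      g <- w$mix_gamma
      k1 <- g * lin + (1 - g) * rbf
      k2 <- g * pol + (1 - g) * rbf
      k3 <- g * lin + (1 - g) * pol
      K[i, j] <- w$alpha1 * k1 + w$alpha2 * k2 + w$alpha3 * k3
    }
  }
  K
}

# PCA oracle: direct eigendecomposition of the sample covariance matrix
pca_oracle <- function(X) {
  e <- eigen(stats::cov(X), symmetric = TRUE)
  list(values = e$values, vectors = e$vectors,
       ratio = e$values / sum(e$values))
}

# Friedman statistic by brute force: within-row ranks (mean ranks for ties)
# and the tie-corrected closed form
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A == C) return(0) # every row fully tied
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
}

# deterministic uniform weights draw on the constraint set
random_weights <- function(seed) {
  with_seed(seed, {
    a <- repair_simplex(runif(3))
    hybrid_weights(a[1], a[2], a[3], runif(1))
  })
}
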