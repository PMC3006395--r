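# Independent oracles used across the tests. These deliberately take the
# dense / brute-force route (full p x p covariances, explicit solves)
# that the package itself avoids, so agreement is a genuine cross-check.

# Dense multivariate normal log density, one row of X at a time.
dense_mvn_loglik <- function(X, mu, Sigma) {
  X <- rbind(X)
  p <- ncol(X)
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  z <- forwardsolve(t(ch), t(X) - mu)
  sum(-0.5 * (p * log(2 * pi) + logdet + colSums(z^2)))
}

# Conditional distribution of u given x under the joint Gaussian
# (u, x) with u ~ N(delta, I), x | u ~ N(W u + mu, sigma2 I), computed
# by dense joint-Gaussian conditioning (never via M^-1 shortcuts).
dense_conditional_posterior <- function(W, mu, sigma2, x, delta) {
  q <- ncol(W)
  C <- W %*% t(W) + diag(sigma2, nrow(W))
  Cinv <- solve(C)
  mean_x <- as.numeric(W %*% delta + mu)
  m <- delta + t(W) %*% Cinv %*% (x - mean_x)
  V <- diag(q) - t(W) %*% Cinv %*% W
  list(mean = as.numeric(m), cov = V)
}

# A centred data matrix whose ML sample covariance crossprod(Xc)/n is
# exactly `C` (n must exceed ncol(C)).
data_with_exact_covariance <- function(C, n, seed = 1) {
  p <- ncol(C)
  stopifnot(n >= p + 1)
  set.seed(seed)
  M <- matrix(rnorm(n * p), n, p)
  K <- qr.Q(qr(cbind(1, M)))[, 2:(p + 1), drop = FALSE]  # orthonormal, sum 0
  e <- eigen(C, symmetric = TRUE)
  Ch <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  sqrt(n) * K %*% Ch
}

# Brute-force jackknife SEs for PPCA loadings: each leave-one-out model
# refitted cold from the closed-form eigendecomposition (independent of
# the package's warm-started engine path), sign-aligned, then the SE
# formula applied entrywise by explicit summation.
brute_force_ppca_jackknife <- function(data, q, W_full) {
  X <- data$values
  n <- nrow(X)
  Ws <- lapply(seq_len(n), function(i) {
    m <- ppca_closed_form(spectral_dataset(X[-i, , drop = FALSE]), q)
    align_loadings(m$W, W_full, method = "sign")
  })
  se <- matrix(0, nrow(W_full), ncol(W_full))
  for (j in seq_len(nrow(W_full))) {
    for (k in seq_len(ncol(W_full))) {
      v <- vapply(Ws, function(w) w[j, k], numeric(1))
      se[j, k] <- sqrt((n - 1) / n * sum((v - mean(v))^2))
    }
  }
  se
}

expect_monotone_trace <- function(trace, slack = 1e-8) {
  expect_true(all(diff(trace) >= -slack))
}
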