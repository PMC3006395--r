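# Internal numerical and RNG helpers shared across the fitting code.

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Aitken acceleration stopping rule on a log-likelihood trace:
# converged when the accelerated estimate of the limit is within `tol`
# of the current value. Needs three points; a numerically flat step is
# treated as converged to avoid division blow-ups.
aitken_converged <- function(ll, tol) {
  k <- length(ll)
  if (k < 3L) return(FALSE)
  d1 <- ll[k - 1L] - ll[k - 2L]
  d2 <- ll[k] - ll[k - 1L]
  if (abs(d2) < 1e-12 * max(1, abs(ll[k]))) return(TRUE)
  cc <- d2 / d1
  if (!is.finite(cc) || cc >= 1) return(FALSE)
  la <- ll[k - 1L] + d2 / (1 - cc)
  abs(la - ll[k]) < tol
}

# Canonicalize a loadings matrix to principal-axes form: W -> U D from its
# SVD, columns ordered by decreasing singular value, sign fixed so each
# column's largest-magnitude entry is positive. Returns the canonical W
# and the orthogonal matrix R with W_canonical = W %*% R; a latent vector
# transforms as u' = t(R) %*% u.
canonicalize_loadings <- function(W) {
  p <- nrow(W)
  q <- ncol(W)
  sv <- svd(W, nu = q, nv = q)
  Wc <- sv$u %*% diag(sv$d, q, q)
  signs <- vapply(seq_len(q), function(k) {
    j <- which.max(abs(Wc[, k]))
    if (Wc[j, k] < 0) -1 else 1
  }, numeric(1))
  Wc <- sweep(Wc, 2L, signs, "*")
  R <- sv$v %*% diag(signs, q, q)
  dimnames(Wc) <- dimnames(W)
  list(W = Wc, rotation = R)
}

# Eigenvalues of the ML sample covariance t(Xc) %*% Xc / n, padded with
# zeros to length p, plus the top-q eigenvectors, via SVD of the centred
# data (cheap when n << p).
sample_cov_spectrum <- function(X, q = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2L, colMeans(X))
  k <- min(n, p)
  nv <- if (is.null(q)) 0L else q
  sv <- svd(Xc, nu = 0L, nv = nv)
  lambda <- c(sv$d^2 / n, rep(0, p - k))[seq_len(p)]
  list(lambda = lambda, vectors = if (nv > 0L) sv$v else NULL,
       rank = sum(sv$d > max(sv$d[1L], 0) * 1e-8))
}

pc_names <- function(q) paste0("PC", seq_len(q))

# 95% (or `level`) posterior ellipse parameters for a 2-D Gaussian with
# covariance `S2`, one row per centre: semi-axes and orientation at the
# chi-squared(2) quantile.
ellipse_params <- function(centers, S2, level, sample_ids) {
  e <- eigen(S2, symmetric = TRUE)
  r <- sqrt(stats::qchisq(level, df = 2) * pmax(e$values, 0))
  angle <- atan2(e$vectors[2L, 1L], e$vectors[1L, 1L])
  data.frame(sample_id = sample_ids,
             x = centers[, 1L], y = centers[, 2L],
             semi_major = r[1L], semi_minor = r[2L], angle = angle,
             row.names = NULL, stringsAsFactors = FALSE)
}
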