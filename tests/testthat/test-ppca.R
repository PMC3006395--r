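test_that("closed-form MLE recovers a noiseless planar structure", {
  set.seed(11)
  n <- 20; p <- 8
  B <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))       # exact 2-plane
  X <- matrix(rnorm(n * 2), n, 2) %*% t(B) + matrix(rnorm(p), n, p, byrow = TRUE)
  m <- ppca_closed_form(spectral_dataset(X), q = 2)
  expect_lt(m$sigma2, 1e-10)
  # sines of the principal angles between span(W) and the plane
  QW <- qr.Q(qr(m$W))
  sines <- svd(QW - B %*% crossprod(B, QW))$d
  expect_true(all(sines < 1e-8))
})

test_that("closed-form MLE matches eigen arithmetic on a fixed covariance", {
  C <- diag(c(5, 3, 1, 1))
  Xc <- data_with_exact_covariance(C, n = 9, seed = 3)
  m <- ppca_closed_form(spectral_dataset(Xc), q = 2)
  expect_equal(m$sigma2, 1, tolerance = 1e-10)
  expect_equal(sqrt(colSums(m$W^2)), c(PC1 = 2, PC2 = sqrt(2)), tolerance = 1e-8)

  # isotropic covariance leaves no signal for the loadings to carry
  Xi <- data_with_exact_covariance(diag(4), n = 9, seed = 4)
  mi <- ppca_closed_form(spectral_dataset(Xi), q = 1)
  expect_lt(sqrt(sum(mi$W^2)), 1e-6)
})

test_that("q outside the feasible range is rejected", {
  sim <- generate_ppca(8, 5, 2, seed = 1)
  expect_error(fit_ppca(sim$data, q = 0), "positive integer")
  expect_error(fit_ppca(sim$data, q = 7), "q < min")
  expect_error(ppca_closed_form(sim$data, q = 5), "q < min")
})

test_that("EM converges to the closed-form MLE from a random start", {
  sim <- generate_ppca(50, 20, 3, sigma2 = 1, eigengap = 6, seed = 21)
  cf <- ppca_closed_form(sim$data, 3)
  f <- fit_ppca(sim$data, 3, init = "random", seed = 5, tol = 1e-11,
                max_iter = 50000)
  expect_true(f$converged)
  expect_lt(max(abs(f$model$W - cf$W)), 1e-4)
  expect_lt(abs(f$model$sigma2 - cf$sigma2) / cf$sigma2, 1e-4)
  expect_monotone_trace(f$loglik_trace)

  # two different random starts reach the same optimum
  f2 <- fit_ppca(sim$data, 3, init = "random", seed = 99, tol = 1e-11,
                 max_iter = 50000)
  expect_equal(f$loglik, f2$loglik, tolerance = 1e-4)
})

test_that("the log-likelihood matches direct dense evaluation", {
  set.seed(31)
  # W = 0: collapses to independent isotropic normals
  d <- generate_ppca(12, 6, 2, seed = 31)$data
  m0 <- probpca:::ppca_model(matrix(0, 6, 2), colMeans(d$values), sigma2 = 1.7)
  direct <- sum(dnorm(sweep(d$values, 2, m0$mu), sd = sqrt(1.7), log = TRUE))
  expect_equal(ppca_loglik(m0, d), direct, tolerance = 1e-8)

  # p = 3, q = 1 against the dense covariance density
  W <- matrix(c(1.2, -0.4, 0.7), 3, 1)
  mu <- c(0.3, -1, 2)
  m <- probpca:::ppca_model(W, mu, sigma2 = 0.6)
  X <- matrix(rnorm(15), 5, 3)
  d3 <- spectral_dataset(X)
  expect_equal(ppca_loglik(m, d3),
               dense_mvn_loglik(X, mu, W %*% t(W) + diag(0.6, 3)),
               tolerance = 1e-8)

  # duplicating every sample doubles the i.i.d. sum
  d6 <- spectral_dataset(rbind(X, X), sample_ids = paste0("s", 1:10))
  expect_equal(ppca_loglik(m, d6), 2 * ppca_loglik(m, d3), tolerance = 1e-10)

  expect_error(ppca_loglik(m, spectral_dataset(matrix(rnorm(20), 5, 4))),
               "bins")
})

test_that("the MLE is a likelihood maximum against random perturbations", {
  sim <- generate_ppca(40, 10, 2, sigma2 = 1, eigengap = 4, seed = 41)
  m <- ppca_closed_form(sim$data, 2)
  ll0 <- ppca_loglik(m, sim$data)
  set.seed(42)
  for (r in 1:100) {
    mp <- m
    mp$W <- m$W + matrix(rnorm(20, sd = 0.02), 10, 2)
    mp$sigma2 <- m$sigma2 * exp(rnorm(1, sd = 0.02))
    expect_lte(ppca_loglik(mp, sim$data), ll0 + 1e-8)
  }
})

test_that("latent posterior matches its closed forms and limits", {
  set.seed(51)
  p <- 5; q <- 2; n <- 7
  W <- matrix(rnorm(p * q), p, q)
  mu <- rnorm(p)
  X <- matrix(rnorm(n * p), n, p)
  d <- spectral_dataset(X)

  # sigma2 -> 0: least-squares projection, vanishing covariance
  m0 <- probpca:::ppca_model(W, mu, sigma2 = 1e-12)
  post0 <- posterior_latent(m0, d)
  ls <- t(solve(crossprod(W), t(sweep(X, 2, mu) %*% W)))
  expect_equal(unname(post0$means), ls, tolerance = 1e-8)
  expect_lt(max(abs(post0$covariance)), 1e-10)

  # orthonormal W, sigma2 = 1: M = 2I
  Wo <- qr.Q(qr(matrix(rnorm(p * q), p, q)))
  m1 <- probpca:::ppca_model(Wo, mu, sigma2 = 1)
  post1 <- posterior_latent(m1, d)
  expect_equal(unname(post1$means), sweep(X, 2, mu) %*% Wo / 2,
               tolerance = 1e-12)
  expect_equal(unname(post1$covariance), diag(q) / 2, tolerance = 1e-12)

  # general case against the dense joint-Gaussian conditioning oracle
  m <- probpca:::ppca_model(W, mu, sigma2 = 0.4)
  post <- posterior_latent(m, d)
  for (i in c(1, 4)) {
    o <- dense_conditional_posterior(W, mu, 0.4, X[i, ], delta = rep(0, q))
    expect_equal(unname(post$means[i, ]), o$mean, tolerance = 1e-10)
    expect_equal(unname(post$covariance), o$cov, tolerance = 1e-10)
  }
  expect_equal(nrow(post$ellipse), n)
  expect_true(all(post$ellipse$semi_major >= post$ellipse$semi_minor))
})

test_that("posterior covariance shrinks as sigma2 decreases (Loewner order)", {
  set.seed(61)
  W <- matrix(rnorm(12), 6, 2)
  mu <- rep(0, 6)
  d <- spectral_dataset(matrix(rnorm(30), 5, 6))
  s2s <- c(2, 1, 0.5, 0.1, 0.01)
  covs <- lapply(s2s, function(s2)
    posterior_latent(probpca:::ppca_model(W, mu, s2), d)$covariance)
  for (k in seq_len(length(s2s) - 1)) {
    dif <- covs[[k]] - covs[[k + 1]]
    expect_true(all(eigen(dif, symmetric = TRUE, only.values = TRUE)$values >
                      -1e-12))
  }
})

test_that("align_loadings undoes sign flips and rotations", {
  set.seed(71)
  W <- matrix(rnorm(16), 8, 2)
  expect_equal(align_loadings(W, W), W, ignore_attr = TRUE)

  flipped <- W %*% diag(c(1, -1))
  expect_equal(align_loadings(flipped, W, method = "sign"), W,
               ignore_attr = TRUE)

  th <- 0.9
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(norm(align_loadings(W %*% R, W) - W, "F"), 1e-10)
  expect_error(align_loadings(W, W[1:4, ]), "identical dimensions")
})
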