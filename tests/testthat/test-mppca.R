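make_mppca <- function(pi, Wl, mu, sigma2) probpca:::mppca_model(pi, Wl, mu, sigma2)

test_that("mixture log-likelihood reduces and matches dense evaluation", {
  set.seed(1)
  p <- 3; q <- 1; n <- 9
  X <- matrix(rnorm(n * p), n, p)
  d <- spectral_dataset(X)
  W1 <- matrix(c(1, -0.5, 0.3), p, q)
  W2 <- matrix(c(0.2, 0.8, -1.1), p, q)
  mu <- rbind(c(0, 0, 0), c(2, -1, 0.5))

  # G = 1 equals the single-component PPCA log-likelihood
  m1 <- make_mppca(1, list(W1), mu[1, , drop = FALSE], 0.6)
  expect_equal(mixture_loglik(m1, d),
               ppca_loglik(probpca:::ppca_model(W1, mu[1, ], 0.6), d),
               tolerance = 1e-10)

  # two identical components: mixing proportions wash out
  m2 <- make_mppca(c(0.3, 0.7), list(W1, W1), mu[c(1, 1), ], 0.6)
  expect_equal(mixture_loglik(m2, d), mixture_loglik(m1, d), tolerance = 1e-10)

  # dense two-component oracle
  m3 <- make_mppca(c(0.4, 0.6), list(W1, W2), mu, 0.6)
  dens <- sapply(seq_len(n), function(i) {
    0.4 * exp(dense_mvn_loglik(X[i, , drop = FALSE], mu[1, ],
                               W1 %*% t(W1) + diag(0.6, p))) +
    0.6 * exp(dense_mvn_loglik(X[i, , drop = FALSE], mu[2, ],
                               W2 %*% t(W2) + diag(0.6, p)))
  })
  expect_equal(mixture_loglik(m3, d), sum(log(dens)), tolerance = 1e-8)
})

test_that("responsibilities follow Bayes' rule", {
  set.seed(2)
  p <- 3; n <- 6
  X <- matrix(rnorm(n * p), n, p)
  d <- spectral_dataset(X)
  W1 <- matrix(rnorm(p), p, 1)
  W2 <- matrix(rnorm(p), p, 1)
  mu <- rbind(rnorm(p), rnorm(p) + 2)

  m1 <- make_mppca(1, list(W1), mu[1, , drop = FALSE], 1)
  expect_equal(unname(responsibilities(m1, d)$z_hat), matrix(1, n, 1))

  # identical components: data carry no information, rows = pi
  mi <- make_mppca(c(0.25, 0.75), list(W1, W1), mu[c(1, 1), ], 1)
  expect_equal(unname(responsibilities(mi, d)$z_hat),
               matrix(c(0.25, 0.75), n, 2, byrow = TRUE), tolerance = 1e-12)

  # general case against direct Bayes computation with dense Gaussians
  m <- make_mppca(c(0.35, 0.65), list(W1, W2), mu, 0.8)
  r <- responsibilities(m, d)
  for (i in c(1, 5)) {
    num <- c(0.35 * exp(dense_mvn_loglik(X[i, , drop = FALSE], mu[1, ],
                                         W1 %*% t(W1) + diag(0.8, p))),
             0.65 * exp(dense_mvn_loglik(X[i, , drop = FALSE], mu[2, ],
                                         W2 %*% t(W2) + diag(0.8, p))))
    expect_equal(unname(r$z_hat[i, ]), num / sum(num), tolerance = 1e-10)
  }
  expect_true(all(abs(rowSums(r$z_hat) - 1) < 1e-12))
  expect_identical(r$labels, unname(apply(r$z_hat, 1, which.max)))
})

test_that("AECM at G = 1 recovers the single PPCA fit", {
  sim <- generate_ppca(25, 10, 2, sigma2 = 1, eigengap = 5, seed = 3)
  fp <- fit_ppca(sim$data, 2, tol = 1e-9)
  fm <- fit_mppca(sim$data, q = 2, G = 1, tol = 1e-9, seed = 1)
  expect_equal(fm$loglik, fp$loglik, tolerance = 1e-6)
  expect_monotone_trace(fm$loglik_trace)
})

test_that("well-separated groups are recovered exactly", {
  sim <- generate_mppca(c(8, 8, 9, 8), p = 40, q = 2, separation = 12,
                        sigma2 = 1, seed = 4)
  f <- fit_mppca(sim$data, q = 2, G = 4, n_starts = 5, seed = 5)
  ct <- cross_tabulate(f$labels, sim$truth$labels)
  expect_equal(ct$ari, 1)
  expect_monotone_trace(f$loglik_trace)
  expect_equal(sum(f$model$pi), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(f$responsibilities$z_hat) - 1) < 1e-12))
})

test_that("component relabelling leaves the likelihood and partition unchanged", {
  sim <- generate_mppca(c(6, 6), p = 12, q = 1, separation = 8, seed = 6)
  f <- fit_mppca(sim$data, q = 1, G = 2, n_starts = 3, seed = 7)
  m <- f$model
  mperm <- make_mppca(m$pi[c(2, 1)], m$W[c(2, 1)], m$mu[c(2, 1), ], m$sigma2)
  expect_equal(mixture_loglik(mperm, sim$data), mixture_loglik(m, sim$data),
               tolerance = 1e-10)
  lab <- responsibilities(m, sim$data)$labels
  labp <- responsibilities(mperm, sim$data)$labels
  expect_equal(cross_tabulate(labp, lab)$ari, 1)
})

test_that("cross tabulation counts and ARI behave", {
  truth <- rep(1:4, c(8, 8, 9, 8))
  ct <- cross_tabulate(truth, truth)
  expect_equal(unname(diag(ct$table)), c(8, 8, 9, 8))
  expect_equal(ct$ari, 1)

  ct0 <- cross_tabulate(rep(1, 33), truth)
  expect_equal(sum(ct0$table != 0), 4L)  # one occupied row
  expect_lte(ct0$ari, 0)

  set.seed(8)
  aris <- replicate(20, cross_tabulate(sample(1:4, 33, TRUE), truth)$ari)
  expect_true(all(abs(aris) < 0.3))
  expect_error(cross_tabulate(1:5, 1:4), "same length")
})
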