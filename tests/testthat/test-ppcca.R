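make_ppcca_model <- function(W, mu, sigma2, alpha, L = ncol(alpha) - 1L) {
  probpca:::ppcca_model(W, mu, sigma2, alpha,
                        covariate_scaling = list(center = rep(0, L),
                                                 scale = rep(1, L),
                                                 standardized = TRUE),
                        covariate_names = if (L > 0) paste0("c", seq_len(L))
                                          else character(0))
}

test_that("latent means are the regression alpha C_i", {
  set.seed(1)
  W <- matrix(rnorm(12), 6, 2)
  # zero regression collapses the latent means to the origin
  m0 <- make_ppcca_model(W, rep(0, 6), 0.5, matrix(0, 2, 3), L = 2)
  lm0 <- latent_means(m0, matrix(rnorm(10), 5, 2))
  expect_true(all(lm0 == 0))

  # intercept-only model: every row equals the intercept column
  mi <- make_ppcca_model(W, rep(0, 6), 0.5, cbind(c(1.5, -2)), L = 0)
  lmi <- latent_means(mi, probpca:::intercept_only_covariates(4))
  expect_equal(unname(lmi), matrix(c(1.5, -2), 4, 2, byrow = TRUE))

  # arithmetic on reported-scale coefficients: intercept 4.08, slope -6.28
  # at a standardized covariate value of 1 gives 4.08 - 6.28 = -2.20
  a <- matrix(c(0, 4.08, 1.34, -6.28), 2, 2)
  m1 <- make_ppcca_model(W, rep(0, 6), 0.5, a, L = 1)
  lm1 <- latent_means(m1, matrix(1, 1, 1))
  expect_equal(lm1[1, 2], -2.20, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(latent_means(m1, matrix(rnorm(6), 3, 2)), "covariate")
})

test_that("intercept-only PPCCA reduces to PPCA", {
  sim <- generate_ppca(30, 12, 2, sigma2 = 1, eigengap = 5, seed = 13)
  d <- preprocess(sim$data)
  fp <- fit_ppca(d, 2, tol = 1e-9)
  fc <- fit_ppcca(d, probpca:::intercept_only_covariates(30), 2, tol = 1e-9)
  expect_equal(fc$loglik, fp$loglik, tolerance = 1e-5)
  expect_equal(fc$model$sigma2, fp$model$sigma2, tolerance = 1e-5)
  expect_lt(max(abs(fc$model$W - fp$model$W)), 1e-3)
  expect_lt(max(abs(fc$model$alpha)), 1e-6)  # centred data: no intercept left
})

test_that("PPCCA EM recovers planted covariate effects", {
  al <- rbind(c(0, 2), c(0, -1))
  sim <- generate_ppcca(100, 30, 2, L = 1, alpha = al, sigma2 = 0.5,
                        eigengap = 6, seed = 2024)
  f <- fit_ppcca(sim$data, sim$covs, 2, tol = 1e-7)
  expect_true(f$converged)
  expect_monotone_trace(f$loglik_trace)
  jk <- jackknife_loadings(f, sim$data, sim$covs)
  # compare in a common basis: map the truth into the fitted basis
  Wt <- align_loadings(sim$truth$W, f$model$W, method = "procrustes")
  a_true <- crossprod(attr(Wt, "rotation"), sim$truth$alpha)
  expect_true(all(abs(f$model$alpha - a_true) < 3 * jk$alpha_se))
})

test_that("fitted parameters are invariant to sample order", {
  al <- rbind(c(0, 1.5))
  sim <- generate_ppcca(40, 10, 1, L = 1, alpha = al, sigma2 = 1,
                        eigengap = 5, seed = 3)
  f1 <- fit_ppcca(sim$data, sim$covs, 1, tol = 1e-9)
  set.seed(4)
  perm <- sample(40)
  dperm <- spectral_dataset(sim$data$values[perm, ],
                            sample_ids = sim$data$sample_ids[perm],
                            bin_labels = sim$data$bin_labels)
  cperm <- covariate_table(sim$covs$raw[perm, , drop = FALSE],
                           standardize = FALSE)
  f2 <- fit_ppcca(dperm, cperm, 1, tol = 1e-9)
  expect_equal(f2$model$W, f1$model$W, tolerance = 1e-6)
  expect_equal(f2$model$alpha, f1$model$alpha, tolerance = 1e-6)
  expect_equal(f2$model$sigma2, f1$model$sigma2, tolerance = 1e-8)
})

test_that("PPCCA scores include the covariate shift and match dense conditioning", {
  set.seed(5)
  p <- 6; q <- 2; n <- 8
  W <- matrix(rnorm(p * q), p, q)
  mu <- rnorm(p)
  alpha <- matrix(c(0.5, -1, 2, 0.3), 2, 2)
  X <- matrix(rnorm(n * p), n, p)
  covs <- covariate_table(rnorm(n), standardize = FALSE)
  d <- spectral_dataset(X)
  m <- make_ppcca_model(W, mu, 0.7, alpha, L = 1)

  sc <- ppcca_scores(m, d, covs)
  delta <- covs$design %*% t(alpha)
  for (i in c(2, 7)) {
    o <- dense_conditional_posterior(W, mu, 0.7, X[i, ], delta[i, ])
    expect_equal(unname(sc$means[i, ]), o$mean, tolerance = 1e-10)
    expect_equal(unname(sc$covariance), o$cov, tolerance = 1e-10)
  }

  # delta = 0 reduces to the PPCA posterior
  m0 <- make_ppcca_model(W, mu, 0.7, matrix(0, 2, 2), L = 1)
  sc0 <- ppcca_scores(m0, d, covs)
  pl <- posterior_latent(probpca:::ppca_model(W, mu, 0.7), d)
  expect_equal(sc0$means, pl$means, tolerance = 1e-12)

  # sigma2 -> 0 kills the covariate contribution: least-squares projection
  mz <- make_ppcca_model(W, mu, 1e-12, alpha, L = 1)
  scz <- ppcca_scores(mz, d, covs)
  ls <- t(solve(crossprod(W), t(sweep(X, 2, mu) %*% W)))
  expect_equal(unname(scz$means), ls, tolerance = 1e-6)
})

test_that("collinear covariates are rejected", {
  sim <- generate_ppca(20, 8, 2, seed = 6)
  cc <- cbind(a = rnorm(20))
  cc <- cbind(cc, b = 2 * cc[, 1])
  expect_error(fit_ppcca(sim$data, covariate_table(cc, standardize = FALSE), 2),
               "rank deficient")
})
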