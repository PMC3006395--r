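test_that("jackknife SE formula reduces correctly", {
  expect_equal(jackknife_se(c(3, 7)), 2)              # |a - b| / 2
  expect_equal(jackknife_se(c(1.3, 1.3, 1.3, 1.3)), 0)
  expect_equal(jackknife_se(1:5), sqrt(8))            # sqrt(4/5 * 10)
  set.seed(1)
  v <- rnorm(17)
  expect_equal(jackknife_se(v), jackknife_se(rev(v))) # order invariance
  expect_error(jackknife_se(3), "at least 2")
  expect_error(jackknife_se(c(1, NA)), "finite")
})

test_that("loading SEs shrink like 1/sqrt(n)", {
  ratio <- sapply(1:4, function(r) {
    s15 <- generate_ppca(15, 10, 2, sigma2 = 1, eigengap = 6, seed = 20 + r)
    s60 <- generate_ppca(60, 10, 2, sigma2 = 1, eigengap = 6, seed = 40 + r)
    f15 <- fit_ppca(s15$data, 2, tol = 1e-9)
    f60 <- fit_ppca(s60$data, 2, tol = 1e-9)
    jk15 <- jackknife_loadings(f15, s15$data)
    jk60 <- jackknife_loadings(f60, s60$data)
    median(jk15$se) / median(jk60$se)
  })
  # quadrupling n should halve the SE, within 30% over replicates
  expect_lt(abs(mean(ratio) - 2), 0.3 * 2)
})

test_that("warm-started jackknife matches the cold brute-force oracle", {
  sim <- generate_ppca(30, 15, 2, sigma2 = 1, eigengap = 6, seed = 3)
  d <- preprocess(sim$data)
  f <- fit_ppca(d, 2, tol = 1e-10)
  jk <- jackknife_loadings(f, d, tol = 1e-10, max_iter = 10000)
  se_bf <- brute_force_ppca_jackknife(d, 2, f$model$W)
  expect_lt(max(abs(jk$se - se_bf)), 1e-5)
  # CI structure
  expect_true(all(jk$ci_low <= f$model$W & f$model$W <= jk$ci_high))
  expect_identical(unname(jk$significant),
                   unname(jk$ci_low > 0 | jk$ci_high < 0))
})

test_that("significant_loadings filters, sorts and nests monotonically", {
  p <- 6
  jk <- structure(list(
    estimate = cbind(c(2.1, -1.5, 0.9, 0.3, -0.05, 1.2)),
    se = cbind(rep(0.1, p)),
    ci_low = cbind(c(1.9, -1.7, 0.7, 0.1, -0.25, -0.1)),
    ci_high = cbind(c(2.3, -1.3, 1.1, 0.5, 0.15, 2.5)),
    significant = cbind(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)),
    bin_labels = paste0("b", 1:p), conf = 0.95, align = "sign",
    n_refits = 10L, n_excluded = 0L), class = "jackknife_result")

  all_sig <- significant_loadings(jk, pc = 1, cutoff = 0)
  expect_identical(all_sig$bin_label, c("b1", "b2", "b3", "b4"))
  expect_identical(significant_loadings(jk, 1, cutoff = 0.8)$bin_label,
                   c("b1", "b2", "b3"))
  expect_identical(nrow(significant_loadings(jk, 1, cutoff = Inf)), 0L)
  # nesting: higher cutoff selects a subset
  for (cuts in list(c(0, 0.5), c(0.5, 1.0), c(0, 2))) {
    s1 <- significant_loadings(jk, 1, cuts[1])$bin_label
    s2 <- significant_loadings(jk, 1, cuts[2])$bin_label
    expect_true(all(s2 %in% s1))
  }
  expect_error(significant_loadings(jk, pc = 2), "between 1 and")
})

test_that("cutoff frequency diagnostics summarise the loading distribution", {
  expect_warning(cf0 <- cutoff_frequency(numeric(3), rep(FALSE, 3)),
                 "no significant")
  expect_identical(nrow(cf0$histogram), 0L)

  cf1 <- cutoff_frequency(rep(0.7, 9), rep(TRUE, 9), n_bins = 10)
  expect_identical(sum(cf1$histogram$count > 0), 1L)

  # bimodal loadings: retained count drops steeply between the modes
  set.seed(4)
  ld <- c(rnorm(60, 0.2, 0.02), rnorm(15, 0.9, 0.02))
  cf2 <- cutoff_frequency(ld, rep(TRUE, 75), n_bins = 30)
  mid <- cf2$retained[cf2$retained$threshold > 0.3 &
                        cf2$retained$threshold < 0.8, "count"]
  expect_true(all(mid == 15))
  expect_true(all(diff(cf2$retained$count) <= 0))

  # uniform loadings: retained at threshold t is about p (1 - t)
  set.seed(5)
  lu <- runif(189)
  cf3 <- cutoff_frequency(lu, rep(TRUE, 189), n_bins = 20)
  expect_true(all(abs(cf3$retained$count - 189 * (1 - cf3$retained$threshold))
                  <= 3 * sqrt(189)))
})

test_that("group tests use Welch t and BH adjustment", {
  set.seed(6)
  base <- matrix(rnorm(9 * 5), 9, 5)
  d_same <- spectral_dataset(rbind(base, base),
                             sample_ids = paste0("s", 1:18))
  g <- rep(c("ctl", "trt"), each = 9)
  res <- group_bin_tests(d_same, g)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))

  # one bin shifted by 10 pooled sds
  X <- matrix(rnorm(18 * 6), 18, 6)
  X[10:18, 3] <- X[10:18, 3] + 10 * sd(X[, 3])
  d <- spectral_dataset(X)
  res2 <- group_bin_tests(d, g)
  expect_lt(res2$p_adjusted[3], 1e-3)
  expect_equal(res2$direction[3], 1)

  # single tested bin: adjustment is a no-op
  res3 <- group_bin_tests(d, g, bins = 3)
  expect_equal(res3$p_adjusted, res3$p)
  # selection by label matches selection by index
  res4 <- group_bin_tests(d, g, bins = d$bin_labels[3])
  expect_equal(res4$p, res3$p)

  expect_error(group_bin_tests(d, rep(c("a", "b", "c"), 6)), "2 levels")
  expect_error(group_bin_tests(d, c("a", rep("b", 17))), "at least 2")
})
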