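# Generators for synthetic spectral datasets with known ground truth.
# Each is a pure function of its arguments (including the seed), so any
# dataset can be regenerated bit-for-bit.

# ppm-style bin labels on a 0.04 ppm grid, skipping the 4.0-6.0 ppm
# water region as is conventional for binned urine/tissue NMR spectra.
ppm_bin_labels <- function(p) {
  grid <- seq(0.52, by = 0.04, length.out = p + 60L)
  grid <- grid[grid < 4.0 | grid > 6.0]
  sprintf("%.2f", grid[seq_len(p)])
}

# Random loadings with exact column norms: orthonormalise a Gaussian
# matrix and rescale the columns, which pins the population eigen-spectrum
# of W W' + sigma2 I exactly.
random_loadings <- function(p, q, colnorms) {
  Q <- qr.Q(qr(matrix(stats::rnorm(p * q), p, q)))
  sweep(Q, 2L, colnorms, "*")
}

# Column norms giving signal eigenvalues sigma2 * (1 + eigengap * j),
# j = q..1: the weakest retained component sits eigengap * sigma2 above
# the noise floor and successive components are spaced by the same gap.
signal_colnorms <- function(q, sigma2, eigengap) {
  sqrt(eigengap * sigma2 * (q:1))
}

#' Generate data from a PPCA model
#'
#' Draws `u_i ~ N_q(0, I)`, then `x_i = W u_i + mu + eps_i` with
#' isotropic noise. `W` has random orthogonal directions with fixed
#' column norms `sqrt(eigengap * sigma2 * (q:1))`, so the population
#' covariance eigenvalues are `sigma2 * (1 + eigengap * j)` for
#' `j = q..1` above a noise floor of `sigma2` -- `eigengap` directly
#' controls how recoverable `q` is.
#'
#' @param n,p,q Sample size, number of bins, latent dimension.
#' @param sigma2 Noise variance (default 1).
#' @param eigengap Spacing of the signal eigenvalues in units of
#'   `sigma2` (default 2).
#' @param seed RNG seed (the generator is a pure function of its
#'   arguments including the seed).
#' @return List with `data` (a [spectral_dataset()]) and `truth`
#'   (list: `kind`, `W`, `mu`, `sigma2`, `scores`, `seed`).
#' @export
generate_ppca <- function(n, p, q, sigma2 = 1, eigengap = 2, seed = NULL) {
  stopifnot(n >= 2, p >= 2, q >= 1, q <= p, sigma2 > 0, eigengap >= 0)
  with_seed(seed, {
    W <- random_loadings(p, q, signal_colnorms(q, sigma2, eigengap))
    mu <- stats::rnorm(p)
    U <- matrix(stats::rnorm(n * q), n, q)
    X <- U %*% t(W) + matrix(mu, n, p, byrow = TRUE) +
      matrix(stats::rnorm(n * p, sd = sqrt(sigma2)), n, p)
    list(data = spectral_dataset(X, bin_labels = ppm_bin_labels(p)),
         truth = list(kind = "ppca", W = W, mu = mu, sigma2 = sigma2,
                      scores = U, seed = seed))
  })
}

#' Generate data from a PPCCA model
#'
#' As [generate_ppca()] but the latent means are covariate-driven:
#' covariates are drawn standard normal, `u_i ~ N_q(alpha C_i, I)` with
#' `C_i = (1, c_i1, ..., c_iL)'`, and `x_i` as in PPCA.
#'
#' @inheritParams generate_ppca
#' @param L Number of covariates.
#' @param alpha q x (L + 1) regression matrix (intercept first column).
#' @return List with `data`, `covs` (a [covariate_table()], kept on the
#'   raw standard-normal scale) and `truth` (including `alpha` and the
#'   drawn covariates).
#' @export
generate_ppcca <- function(n, p, q, L = 1, alpha, sigma2 = 1, eigengap = 2,
                           seed = NULL) {
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != q || ncol(alpha) != L + 1L)
    stop("'alpha' must be a q x (L + 1) matrix", call. = FALSE)
  stopifnot(n >= 2, p >= 2, q >= 1, sigma2 > 0)
  with_seed(seed, {
    W <- random_loadings(p, q, signal_colnorms(q, sigma2, eigengap))
    mu <- stats::rnorm(p)
    C <- matrix(stats::rnorm(n * L), n, L)
    delta <- cbind(1, C) %*% t(alpha)
    U <- delta + matrix(stats::rnorm(n * q), n, q)
    X <- U %*% t(W) + matrix(mu, n, p, byrow = TRUE) +
      matrix(stats::rnorm(n * p, sd = sqrt(sigma2)), n, p)
    list(data = spectral_dataset(X, bin_labels = ppm_bin_labels(p)),
         covs = covariate_table(C, standardize = FALSE),
         truth = list(kind = "ppcca", W = W, mu = mu, sigma2 = sigma2,
                      alpha = alpha, covariates = C, scores = U, seed = seed))
  })
}

#' Generate data from a mixture of PPCA models
#'
#' Group means are placed at scaled standard-basis vectors so every pair
#' of means is exactly `separation * sqrt(sigma2)` apart; each group has
#' its own random loadings with the fixed column norms of
#' [generate_ppca()], and the noise variance is shared.
#'
#' @inheritParams generate_ppca
#' @param n_per_group Integer vector of group sizes (length G).
#' @param separation Distance between every pair of group means in units
#'   of the noise standard deviation (default 10).
#' @return List with `data` and `truth` (including `labels`, `pi`,
#'   per-group `W` and `mu`).
#' @export
generate_mppca <- function(n_per_group, p, q, separation = 10, sigma2 = 1,
                           eigengap = 2, seed = NULL) {
  G <- length(n_per_group)
  stopifnot(G >= 1, all(n_per_group >= 1), p >= max(G, 2), q >= 1,
            separation >= 0, sigma2 > 0)
  n <- sum(n_per_group)
  with_seed(seed, {
    offset <- stats::rnorm(p)
    d <- separation * sqrt(sigma2) / sqrt(2)
    mu <- matrix(offset, G, p, byrow = TRUE)
    for (g in seq_len(G)) mu[g, g] <- mu[g, g] + d
    Wl <- lapply(seq_len(G), function(g)
      random_loadings(p, q, signal_colnorms(q, sigma2, eigengap)))
    labels <- rep(seq_len(G), n_per_group)
    X <- matrix(0, n, p)
    for (g in seq_len(G)) {
      idx <- which(labels == g)
      U <- matrix(stats::rnorm(length(idx) * q), length(idx), q)
      X[idx, ] <- U %*% t(Wl[[g]]) + matrix(mu[g, ], length(idx), p,
                                            byrow = TRUE) +
        matrix(stats::rnorm(length(idx) * p, sd = sqrt(sigma2)),
               length(idx), p)
    }
    list(data = spectral_dataset(X, bin_labels = ppm_bin_labels(p)),
         truth = list(kind = "mppca", W = Wl, mu = mu, sigma2 = sigma2,
                      labels = labels, pi = n_per_group / n, seed = seed))
  })
}

#' Urine-study-like synthetic fixture
#'
#' An 18 x 189 two-group dataset emulating a binned urinary NMR study:
#' 9 treated and 9 control spectra over 189 ppm-labelled bins, with
#' (i) a treatment effect planted on the first latent dimension, carried
#' by 17 designated bins with large PC1 loadings, and (ii) a body-weight
#' covariate acting on the second latent dimension only. Five latent
#' dimensions carry signal. Intensities are generated as an exponentiated
#' (scaled) Gaussian field, giving positive, log-normal-ish bin
#' intensities: a deliberate mild misspecification stressor, since the
#' PPCA model is then only approximately correct after centring.
#'
#' @param seed RNG seed.
#' @return List with `data` (positive raw intensities; centre with
#'   [preprocess()] before fitting), `groups` (factor control/treated),
#'   `covs` (a [covariate_table()] of raw body weight, standardized),
#'   and `truth` (planted bin indices and labels, the covariate
#'   dimension, the latent effect sizes and the underlying Gaussian-field
#'   parameters).
#' @export
generate_urine_like <- function(seed = NULL) {
  n <- 18L
  p <- 189L
  q <- 5L
  n_planted <- 17L
  treat_shift <- 4      # latent-sd separation of the groups on dimension 1
  weight_slope <- 2     # latent effect of standardized weight on dimension 2
  sigma2 <- 0.05
  s <- 0.05             # exponentiation scale of the log-normal-ish field
  with_seed(seed, {
    labels <- ppm_bin_labels(p)
    planted_idx <- round(seq(15L, p - 15L, length.out = n_planted))
    # PC1: large loadings of mixed sign on the planted bins, near-zero noise
    # loadings elsewhere
    w1 <- stats::rnorm(p, sd = 0.05)
    w1[planted_idx] <- seq(2.2, 0.9, length.out = n_planted) *
      rep_len(c(1, -1), n_planted)
    # dimensions 2..5: random directions with decreasing strength; the
    # norms are spaced so that neither the marginal (PPCA) nor the
    # conditional (PPCCA) eigen-structure has near-ties, keeping the
    # principal axes stably identified at n = 18
    W <- cbind(w1, random_loadings(p, q - 1L, c(3.5, 2.4, 2.0, 1.7)))
    groups <- factor(rep(c("control", "treated"), each = 9L),
                     levels = c("control", "treated"))
    weight_z <- stats::rnorm(n)
    weight_raw <- 28 + 2 * weight_z
    U <- matrix(stats::rnorm(n * q), n, q)
    U[, 1L] <- U[, 1L] + ifelse(groups == "treated", 1, -1) * treat_shift / 2
    U[, 2L] <- U[, 2L] + weight_slope * weight_z
    mu0 <- stats::rnorm(p, sd = 0.5)
    Z <- U %*% t(W) + matrix(mu0, n, p, byrow = TRUE) +
      matrix(stats::rnorm(n * p, sd = sqrt(sigma2)), n, p)
    X <- exp(s * Z) / s
    alpha <- matrix(0, q, 2L)
    alpha[2L, 2L] <- weight_slope
    list(data = spectral_dataset(X, bin_labels = labels),
         groups = groups,
         covs = covariate_table(weight_raw, names = "weight",
                                standardize = TRUE),
         truth = list(kind = "urine-like", q = q, W = W, mu = mu0,
                      sigma2 = sigma2, exp_scale = s,
                      planted_idx = planted_idx,
                      planted_bins = labels[planted_idx],
                      covariate_dim = 2L, alpha = alpha,
                      treat_shift = treat_shift, seed = seed))
  })
}

#' Brain-study-like synthetic fixture
#'
#' A 33 x 164 four-group dataset emulating binned NMR spectra from four
#' brain regions (8/8/9/8 samples), generated from a mixture of PPCA
#' models with q = 2 per group and group means 12 noise-sd apart, so a
#' mixture fit at G = 4 should recover the regions exactly.
#'
#' @param seed RNG seed.
#' @param separation Pairwise distance between group means in noise-sd
#'   units (default 12).
#' @return List with `data`, `regions` (factor of true region labels)
#'   and `truth` as in [generate_mppca()].
#' @export
generate_brain_like <- function(seed = NULL, separation = 12) {
  regions <- c("cerebellum", "brainstem", "prefrontal.cortex", "hippocampus")
  sim <- generate_mppca(n_per_group = c(8L, 8L, 9L, 8L), p = 164L, q = 2L,
                        separation = separation, sigma2 = 1, seed = seed)
  sim$regions <- factor(regions[sim$truth$labels], levels = regions)
  sim$truth$kind <- "brain-like"
  sim
}
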