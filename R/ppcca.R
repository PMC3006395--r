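#' @rdname ppca_model
#' @param alpha q x (L + 1) regression matrix: row k holds the intercept
#'   and covariate slopes for latent dimension k.
#' @param covariate_scaling Centring/scaling record used to standardize
#'   covariates (as stored in a [covariate_table()]).
#' @param covariate_names Covariate names.
#' @keywords internal
ppcca_model <- function(W, mu, sigma2, alpha, covariate_scaling,
                        covariate_names) {
  base <- ppca_model(W, mu, sigma2)
  alpha <- as.matrix(alpha)
  stopifnot(nrow(alpha) == base$q, all(is.finite(alpha)))
  dimnames(alpha) <- list(pc_names(base$q),
                          c("intercept", covariate_names))
  base$alpha <- alpha
  base$L <- ncol(alpha) - 1L
  base$covariate_scaling <- covariate_scaling
  base$covariate_names <- covariate_names
  class(base) <- c("ppcca_model", "ppca_model")
  base
}

#' @export
print.ppcca_model <- function(x, ...) {
  cat(sprintf("PPCCA model: p = %d bins, q = %d components, L = %d covariate(s), sigma2 = %.4g\n",
              nrow(x$W), x$q, x$L, x$sigma2))
  cat("Regression parameters (alpha):\n")
  print(round(x$alpha, 3))
  invisible(x)
}

# Resolve user-supplied covariates against a fitted PPCCA model's stored
# scaling, returning the n x (L + 1) design matrix.
model_design <- function(model, covs, n = NULL) {
  if (inherits(covs, "covariate_table")) {
    des <- covs$design
  } else {
    if (is.null(model$covariate_scaling))
      stop("model carries no covariate scaling record; supply a covariate_table",
           call. = FALSE)
    x <- covs
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    x <- as.matrix(x)
    sc <- model$covariate_scaling
    std <- sweep(sweep(x, 2L, sc$center), 2L, sc$scale, "/")
    des <- cbind(1, std)
  }
  if (ncol(des) != ncol(model$alpha))
    stop(sprintf("model expects %d covariate(s) but %d supplied",
                 ncol(model$alpha) - 1L, ncol(des) - 1L), call. = FALSE)
  if (!is.null(n) && nrow(des) != n)
    stop("covariate rows do not match the number of samples", call. = FALSE)
  des
}

#' Covariate-driven latent means
#'
#' Under the PPCCA model the latent variable of sample i is centred at
#' `delta_i = alpha C_i`, where `C_i` is the design vector (intercept
#' plus standardized covariates). Returns the n x q matrix of these
#' means.
#'
#' @param model A `ppcca_model`.
#' @param covs A [covariate_table()] or raw covariate values (which are
#'   standardized with the model's stored scaling).
#' @return n x q matrix with row i equal to `alpha C_i`.
#' @export
latent_means <- function(model, covs) {
  des <- model_design(model, covs)
  delta <- des %*% t(model$alpha)
  colnames(delta) <- pc_names(model$q)
  delta
}

# PPCCA observed-data log-likelihood given the design matrix: samples are
# independent N_p(W delta_i + mu, W W' + sigma2 I).
ppcca_loglik_engine <- function(X, des, W, mu, alpha, s2) {
  n <- nrow(X)
  p <- ncol(X)
  q <- ncol(W)
  M <- crossprod(W)
  diag(M) <- diag(M) + s2
  ch <- chol(M)
  Minv <- chol2inv(ch)
  delta <- des %*% t(alpha)
  Resid <- sweep(X, 2L, mu) - delta %*% t(W)
  RW <- Resid %*% W
  quad <- (sum(Resid^2) - sum((RW %*% Minv) * RW)) / s2
  -0.5 * (n * p * log(2 * pi) + n * ((p - q) * log(s2) + 2 * sum(log(diag(ch)))) +
            quad)
}

#' PPCCA observed-data log-likelihood
#'
#' @param model A `ppcca_model`.
#' @param data A [spectral_dataset()].
#' @param covs Covariates as in [latent_means()].
#' @return The log-likelihood (scalar).
#' @export
ppcca_loglik <- function(model, data, covs) {
  data <- as_spectral_dataset(data)
  des <- model_design(model, covs, n = nrow(data$values))
  ppcca_loglik_engine(data$values, des, model$W, model$mu, model$alpha,
                      model$sigma2)
}

# PPCCA EM engine. E-step: posterior N(M^-1[W'(x - mu) + s2 delta], s2 M^-1).
# M-steps (conditional maximisations, each in closed form): alpha by least
# squares of the posterior means on the design; W given alpha; sigma2 from
# the expected residual sum of squares (or its inverse-gamma posterior
# mode when map = TRUE). The mean mu is fixed at the sample mean, as in
# PPCA: updating it jointly with alpha would leave the intercept column
# of alpha unidentified (the likelihood is flat along
# (alpha_0, mu) -> (alpha_0 + a, mu - W a)).
ppcca_em_engine <- function(X, des, q, W0, alpha0, s0, max_iter, tol,
                            map = FALSE, prior = NULL, floor = 1e-10) {
  n <- nrow(X)
  p <- ncol(X)
  W <- as.matrix(W0)
  alpha <- as.matrix(alpha0)
  s2 <- max(s0, floor)   # a floored start is legal; MAP updates can lift it
  floored <- FALSE
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sumXc2 <- sum(Xc^2)
  # When p >> n, every EM iterate of W lies in the row space of Xc, so
  # the whole iteration can run in the min(n, p)-dimensional basis of
  # right singular vectors: identical likelihood and updates (p enters
  # the likelihood only through the explicit (p - q) log sigma2 and
  # n p log 2 pi terms), at a fraction of the per-iteration cost.
  Vred <- NULL
  if (p > 1.5 * n) {
    Vred <- svd(Xc, nu = 0L, nv = min(n, p))$v
    Xc <- Xc %*% Vred
    W <- crossprod(Vred, W)
  }
  CtC <- crossprod(des)
  ll_trace <- numeric(0)
  obj_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  Iq <- diag(q)
  repeat {
    M <- crossprod(W)
    diag(M) <- diag(M) + s2
    ch <- chol(M)
    Minv <- chol2inv(ch)
    delta <- des %*% t(alpha)
    XcW <- Xc %*% W
    RW <- XcW - delta %*% (M - s2 * Iq)    # (Xc - delta W') W
    quad <- (sumXc2 - 2 * sum(XcW * delta) + sum((delta %*% crossprod(W)) * delta) -
               sum((RW %*% Minv) * RW)) / s2
    ll <- -0.5 * (n * p * log(2 * pi) +
                    n * ((p - q) * log(s2) + 2 * sum(log(diag(ch)))) + quad)
    ll_trace <- c(ll_trace, ll)
    obj_trace <- c(obj_trace, if (map) ll + log_invgamma(s2, prior) else ll)
    if (aitken_converged(obj_trace, tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    # E-step moments
    Umean <- (XcW + s2 * delta) %*% Minv
    Suu <- n * s2 * Minv + crossprod(Umean)
    # CM-steps
    alpha <- t(solve(CtC, crossprod(des, Umean)))
    A <- crossprod(Xc, Umean)
    W <- A %*% chol2inv(chol((Suu + t(Suu)) / 2))
    rss <- sumXc2 - 2 * sum(A * W) + sum(crossprod(W) * Suu)
    s2 <- if (map)
      (rss / 2 + prior$scale) / (n * p / 2 + prior$shape + 1)
    else rss / (n * p)
    if (!is.finite(s2) || s2 < floor) {
      s2 <- floor
      floored <- TRUE
      break
    }
  }
  if (!is.null(Vred)) W <- Vred %*% W
  list(W = W, mu = mu, alpha = alpha, sigma2 = s2,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged, n_iter = iter, sigma2_floor = floored)
}

# Canonicalise a PPCCA solution: rotate W to principal axes and carry the
# same orthogonal transform into alpha so delta_i (hence the fit) is
# unchanged.
canonicalize_ppcca <- function(W, alpha) {
  cn <- canonicalize_loadings(W)
  list(W = cn$W, alpha = t(cn$rotation) %*% alpha)
}

#' Fit a PPCCA model by the EM algorithm
#'
#' Probabilistic principal components and covariates analysis: PPCA in
#' which the latent mean of sample i is `delta_i = alpha C_i`, a linear
#' function of an intercept and L observed covariates, so covariates may
#' shift a sample's position in the principal subspace dimension by
#' dimension. Estimation alternates the latent posterior E-step with
#' closed-form conditional M-steps (the `alpha` update is the least
#' squares regression of the posterior latent means on the design
#' matrix). Convergence uses Aitken's acceleration; loadings are
#' canonicalised as in [fit_ppca()] with `alpha` rotated consistently so
#' fitted latent means are invariant.
#'
#' @inheritParams fit_ppca
#' @param covs A [covariate_table()], or raw covariate values (vector /
#'   matrix / data frame), standardized by default.
#' @return An object of class `ppcca_fit`; as [fit_ppca()] plus the
#'   fitted `ppcca_model` (with `alpha`) and `L`.
#' @seealso [ppcca_scores()], [latent_means()], [jackknife_loadings()]
#' @export
fit_ppcca <- function(data, covs, q, max_iter = 1000, tol = 1e-4,
                      init = c("eigen", "random"), seed = NULL, prior = NULL,
                      sigma2_floor = 1e-10) {
  data <- as_spectral_dataset(data)
  init <- match.arg(init)
  X <- data$values
  n <- nrow(X)
  p <- ncol(X)
  check_q(q, n, p)
  if (!inherits(covs, "covariate_table")) covs <- covariate_table(covs)
  des <- covs$design
  if (nrow(des) != n)
    stop("covariate rows (", nrow(des), ") do not match samples (", n, ")",
         call. = FALSE)
  if (qr(des)$rank < ncol(des))
    stop("design matrix is rank deficient (collinear covariates)", call. = FALSE)
  L <- ncol(des) - 1L

  sp <- sample_cov_spectrum(X, q)
  if (is.null(prior)) prior <- default_sigma2_prior(sp$lambda)
  ini <- init_ppca(X, q, init, seed, sp, sigma2_floor)
  mu0 <- colMeans(X)
  # start alpha at the regression of the initial latent scores on C
  M0 <- crossprod(ini$W0)
  diag(M0) <- diag(M0) + max(ini$s0, sigma2_floor)
  U0 <- sweep(X, 2L, mu0) %*% ini$W0 %*% chol2inv(chol(M0))
  alpha0 <- t(solve(crossprod(des), crossprod(des, U0)))

  ml <- ppcca_em_engine(X, des, q, ini$W0, alpha0, ini$s0, max_iter, tol,
                        map = FALSE, floor = sigma2_floor)
  cn_ml <- canonicalize_ppcca(ml$W, ml$alpha)
  rownames(cn_ml$W) <- data$bin_labels

  warm <- if (ml$sigma2_floor)
    list(W = ini$W0, alpha = alpha0, sigma2 = ini$s0)
  else ml
  mp <- ppcca_em_engine(X, des, q, warm$W, warm$alpha, warm$sigma2,
                        max_iter, tol, map = TRUE, prior = prior,
                        floor = sigma2_floor)
  cn_mp <- canonicalize_ppcca(mp$W, mp$alpha)
  rownames(cn_mp$W) <- data$bin_labels

  K <- count_params("ppcca", p = p, q = q, L = L)
  structure(list(
    model = ppcca_model(cn_ml$W, ml$mu, ml$sigma2, cn_ml$alpha,
                        covs$scaling, covs$names),
    loglik = ml$loglik,
    loglik_trace = ml$loglik_trace,
    converged = ml$converged,
    n_iter = ml$n_iter,
    bic = bic(ml$loglik, K, n),
    modified_bic = bic(mp$loglik, K, n),
    prop_var = sum(sp$lambda[seq_len(q)]) / sum(sp$lambda),
    sigma2_floor = ml$sigma2_floor,
    map = list(model = ppcca_model(cn_mp$W, mp$mu, mp$sigma2, cn_mp$alpha,
                                   covs$scaling, covs$names),
               loglik = mp$loglik, converged = mp$converged,
               sigma2_floor = mp$sigma2_floor),
    prior = prior, covariates = covs, n = n, p = p, q = q, L = L,
    kind = "ppcca"),
    class = "ppcca_fit")
}

#' @export
print.ppcca_fit <- function(x, ...) {
  cat(sprintf("PPCCA fit: n = %d, p = %d, q = %d, L = %d covariate(s)\n",
              x$n, x$p, x$q, x$L))
  cat(sprintf("  loglik %.3f after %d EM iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  BIC %.2f | modified BIC %.2f | prop. variance %.3f\n",
              x$bic, x$modified_bic, x$prop_var))
  cat("Regression parameters (alpha):\n")
  print(round(x$model$alpha, 3))
  invisible(x)
}

#' PPCCA latent posterior (covariate-adjusted scores)
#'
#' Posterior of the latent variable under PPCCA:
#' `N_q(M^{-1}[W'(x - mu) + sigma2 delta_i], sigma2 M^{-1})`. The score
#' depends on both the spectrum and the sample's covariates through
#' `delta_i`; as `sigma2 -> 0` the covariate contribution vanishes and
#' the score reduces to the least-squares projection.
#'
#' @inheritParams posterior_latent
#' @param model A `ppcca_model`.
#' @param covs Covariates as in [latent_means()].
#' @return A `latent_posterior` (see [posterior_latent()]).
#' @export
ppcca_scores <- function(model, data, covs, level = 0.95, dims = c(1L, 2L)) {
  data <- as_spectral_dataset(data)
  stopifnot(level > 0, level < 1)
  X <- data$values
  des <- model_design(model, covs, n = nrow(X))
  W <- model$W
  q <- model$q
  s2 <- model$sigma2
  M <- crossprod(W)
  diag(M) <- diag(M) + s2
  Minv <- chol2inv(chol(M))
  delta <- des %*% t(model$alpha)
  means <- (sweep(X, 2L, model$mu) %*% W + s2 * delta) %*% Minv
  covv <- s2 * Minv
  covv <- (covv + t(covv)) / 2
  dimnames(means) <- list(data$sample_ids, pc_names(q))
  dimnames(covv) <- list(pc_names(q), pc_names(q))
  ell <- NULL
  if (q >= 2L) {
    dims <- as.integer(dims)
    stopifnot(length(dims) == 2L, all(dims >= 1L), all(dims <= q))
    ell <- ellipse_params(means[, dims, drop = FALSE], covv[dims, dims],
                          level, data$sample_ids)
  }
  structure(list(means = means, covariance = covv, level = level,
                 ellipse = ell), class = "latent_posterior")
}
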