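#' Probabilistic PCA model objects
#'
#' A `ppca_model` represents the Gaussian latent-variable model
#' \deqn{x_i = W u_i + \mu + \epsilon_i,\qquad u_i \sim N_q(0, I),\qquad
#'       \epsilon_i \sim N_p(0, \sigma^2 I),}
#' whose maximum-likelihood loadings span the conventional PCA subspace.
#' Objects hold the p x q loadings `W`, the mean `mu`, the isotropic noise
#' variance `sigma2` and the latent dimension `q`.
#'
#' @param W Numeric p x q loadings matrix.
#' @param mu Numeric length-p mean vector.
#' @param sigma2 Non-negative noise variance.
#' @return An object of class `ppca_model`.
#' @keywords internal
ppca_model <- function(W, mu, sigma2) {
  W <- as.matrix(W)
  q <- ncol(W)
  stopifnot(length(mu) == nrow(W), is.finite(sigma2), sigma2 >= 0)
  colnames(W) <- pc_names(q)
  structure(list(W = W, mu = mu, sigma2 = sigma2, q = q), class = "ppca_model")
}

#' @export
print.ppca_model <- function(x, ...) {
  cat(sprintf("PPCA model: p = %d bins, q = %d components, sigma2 = %.4g\n",
              nrow(x$W), x$q, x$sigma2))
  invisible(x)
}

#' Closed-form maximum-likelihood PPCA fit
#'
#' The exact MLE of the PPCA model from the eigendecomposition of the
#' sample covariance: `sigma2` is the mean of the p - q discarded
#' eigenvalues and the loadings are the top-q eigenvectors scaled by
#' `sqrt(eigenvalue - sigma2)`. The returned loadings are in
#' principal-axes form (columns ordered by decreasing eigenvalue, the
#' largest-magnitude entry of each column positive), so they coincide with
#' conventional PCA loadings. Serves as the oracle against which the EM
#' fit of [fit_ppca()] can be checked.
#'
#' @param data A [spectral_dataset()] (or matrix).
#' @param q Number of principal components, `1 <= q < rank` of the
#'   centred data.
#' @return A `ppca_model`.
#' @export
ppca_closed_form <- function(data, q) {
  data <- as_spectral_dataset(data)
  X <- data$values
  n <- nrow(X)
  p <- ncol(X)
  check_q(q, n, p)
  sp <- sample_cov_spectrum(X, q)
  if (q > sp$rank)
    stop(sprintf("q = %d exceeds the rank (%d) of the centred data",
                 q, sp$rank), call. = FALSE)
  lambda <- sp$lambda
  sigma2 <- mean(lambda[(q + 1L):p])
  scale <- sqrt(pmax(lambda[seq_len(q)] - sigma2, 0))
  W <- sweep(sp$vectors, 2L, scale, "*")
  W <- fix_column_signs(W)
  rownames(W) <- data$bin_labels
  ppca_model(W, colMeans(X), sigma2)
}

fix_column_signs <- function(W) {
  for (k in seq_len(ncol(W))) {
    j <- which.max(abs(W[, k]))
    if (length(j) && W[j, k] < 0) W[, k] <- -W[, k]
  }
  W
}

check_q <- function(q, n, p) {
  if (length(q) != 1L || q < 1L || q != round(q))
    stop("'q' must be a positive integer", call. = FALSE)
  if (q >= min(n - 1L, p))
    stop(sprintf("q = %d too large for n = %d samples, p = %d bins (need q < min(n - 1, p))",
                 q, n, p), call. = FALSE)
  invisible(q)
}

# Log of the inverse-gamma prior density at s2 (unnormalised terms kept
# so that the penalised EM objective is a genuine log posterior).
log_invgamma <- function(s2, prior) {
  prior$shape * log(prior$scale) - lgamma(prior$shape) -
    (prior$shape + 1) * log(s2) - prior$scale / s2
}

# Core PPCA EM engine on a raw data matrix. Never materialises a p x p
# covariance: all steps use t(Xc) %*% (Xc %*% W) products, O(npq) per
# iteration. With map = TRUE the sigma2 M-step is the posterior mode
# under the inverse-gamma prior and Aitken convergence is monitored on
# the log posterior.
ppca_em_engine <- function(X, q, W0, s0, max_iter, tol, map = FALSE,
                           prior = NULL, floor = 1e-10) {
  n <- nrow(X)
  p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  trS <- sum(Xc^2) / n
  W <- as.matrix(W0)
  s2 <- max(s0, floor)   # a floored start is legal; MAP updates can lift it
  floored <- FALSE
  ll_trace <- numeric(0)
  obj_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    M <- crossprod(W)
    diag(M) <- diag(M) + s2
    ch <- chol(M)
    Minv <- chol2inv(ch)
    logdetM <- 2 * sum(log(diag(ch)))
    XW <- Xc %*% W
    SW <- crossprod(Xc, XW) / n
    WtSW <- crossprod(W, SW)
    ll <- -n / 2 * (p * log(2 * pi) + (p - q) * log(s2) + logdetM +
                      (trS - sum(Minv * WtSW)) / s2)
    ll_trace <- c(ll_trace, ll)
    obj_trace <- c(obj_trace, if (map) ll + log_invgamma(s2, prior) else ll)
    if (aitken_converged(obj_trace, tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    Wnew <- SW %*% solve(s2 * diag(q) + Minv %*% WtSW)
    s2_ml <- (trS - sum((SW %*% Minv) * Wnew)) / p
    s2 <- if (map)
      (n * p * s2_ml / 2 + prior$scale) / (n * p / 2 + prior$shape + 1)
    else s2_ml
    W <- Wnew
    if (!is.finite(s2) || s2 < floor) {
      # likelihood singularity: clamp, flag, and stop rather than let the
      # trace ride the divergence
      s2 <- floor
      floored <- TRUE
      break
    }
  }
  list(W = W, mu = mu, sigma2 = s2, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, converged = converged, n_iter = iter,
       sigma2_floor = floored)
}

init_ppca <- function(X, q, init, seed, spectrum, floor) {
  n <- nrow(X)
  p <- ncol(X)
  if (init == "eigen") {
    s0 <- mean(spectrum$lambda[(q + 1L):p])
    scale <- sqrt(pmax(spectrum$lambda[seq_len(q)] - s0, 0))
    W0 <- sweep(spectrum$vectors, 2L, scale, "*")
  } else {
    vbar <- sum(spectrum$lambda) / p
    W0 <- with_seed(seed, matrix(stats::rnorm(p * q), p, q)) * sqrt(vbar / q)
    s0 <- vbar / 2
  }
  list(W0 = W0, s0 = s0)
}

#' Fit a PPCA model by the EM algorithm
#'
#' Maximum-likelihood estimation of the PPCA model. The E-step computes
#' the latent posterior moments from the current parameters; the M-step
#' updates `W` and `sigma2` in closed form. Convergence is assessed by
#' Aitken's acceleration on the log-likelihood. The fitted loadings are
#' canonicalised to principal-axes form, so at convergence they match
#' [ppca_closed_form()] (EM is identified only up to an orthogonal
#' rotation otherwise).
#'
#' Alongside the ML fit, a second EM run replaces the `sigma2` M-step
#' with the posterior mode under a conjugate inverse-gamma prior; the
#' BIC evaluated at that MAP estimate (`modified_bic`) is the model
#' selection criterion recommended when `n` is much smaller than `p`,
#' where the plain criterion can be destabilised by likelihood
#' singularities.
#'
#' @param data A [spectral_dataset()] (or matrix), normally centred with
#'   [preprocess()].
#' @param q Number of principal components.
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Aitken convergence tolerance on the log-likelihood
#'   (default 1e-4).
#' @param init `"eigen"` (closed-form start; deterministic, default) or
#'   `"random"`.
#' @param seed RNG seed for random initialisation.
#' @param prior A [sigma2_prior()] for the MAP run; defaults to
#'   `sigma2_prior(3, 2 * vbar)` with `vbar` the mean per-bin variance.
#' @param sigma2_floor Numerical floor for `sigma2`; reaching it flags a
#'   likelihood singularity (`sigma2_floor = TRUE` in the result).
#'
#' @return An object of class `ppca_fit` with elements `model`
#'   (a `ppca_model`), `loglik`, `loglik_trace`, `converged`, `n_iter`,
#'   `bic`, `modified_bic`, `prop_var`, `sigma2_floor`, `map`
#'   (the MAP-sigma2 refit) and `prior`.
#' @seealso [ppca_closed_form()], [posterior_latent()], [select_model()]
#' @examples
#' sim <- generate_ppca(n = 40, p = 12, q = 2, seed = 1)
#' fit <- fit_ppca(sim$data, q = 2)
#' fit$prop_var
#' @export
fit_ppca <- function(data, q, max_iter = 1000, tol = 1e-4,
                     init = c("eigen", "random"), seed = NULL, prior = NULL,
                     sigma2_floor = 1e-10) {
  data <- as_spectral_dataset(data)
  init <- match.arg(init)
  X <- data$values
  n <- nrow(X)
  p <- ncol(X)
  check_q(q, n, p)
  sp <- sample_cov_spectrum(X, q)
  if (is.null(prior)) prior <- default_sigma2_prior(sp$lambda)
  ini <- init_ppca(X, q, init, seed, sp, sigma2_floor)

  ml <- ppca_em_engine(X, q, ini$W0, ini$s0, max_iter, tol,
                       map = FALSE, floor = sigma2_floor)
  W_ml <- canonicalize_loadings(ml$W)$W
  rownames(W_ml) <- data$bin_labels

  if (ml$sigma2_floor) {
    map0 <- ini
  } else {
    map0 <- list(W0 = ml$W, s0 = ml$sigma2)
  }
  mp <- ppca_em_engine(X, q, map0$W0, map0$s0, max_iter, tol,
                       map = TRUE, prior = prior, floor = sigma2_floor)
  W_mp <- canonicalize_loadings(mp$W)$W
  rownames(W_mp) <- data$bin_labels

  K <- count_params("ppca", p = p, q = q)
  structure(list(
    model = ppca_model(W_ml, ml$mu, ml$sigma2),
    loglik = ml$loglik,
    loglik_trace = ml$loglik_trace,
    converged = ml$converged,
    n_iter = ml$n_iter,
    bic = bic(ml$loglik, K, n),
    modified_bic = bic(mp$loglik, K, n),
    prop_var = sum(sp$lambda[seq_len(q)]) / sum(sp$lambda),
    sigma2_floor = ml$sigma2_floor,
    map = list(model = ppca_model(W_mp, mp$mu, mp$sigma2),
               loglik = mp$loglik, converged = mp$converged,
               sigma2_floor = mp$sigma2_floor),
    prior = prior, n = n, p = p, q = q, kind = "ppca"),
    class = "ppca_fit")
}

#' @export
print.ppca_fit <- function(x, ...) {
  cat(sprintf("PPCA fit: n = %d, p = %d, q = %d\n", x$n, x$p, x$q))
  cat(sprintf("  loglik %.3f after %d EM iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  BIC %.2f | modified BIC %.2f | prop. variance %.3f\n",
              x$bic, x$modified_bic, x$prop_var))
  if (x$sigma2_floor)
    cat("  warning: sigma2 hit its numerical floor (likelihood singularity)\n")
  invisible(x)
}

#' PPCA observed-data log-likelihood
#'
#' Sum over samples of the log predictive density
#' `N_p(mu, W W' + sigma2 I)`, evaluated through the q-dimensional
#' Woodbury/determinant-lemma forms so no p x p inverse is formed.
#'
#' @param model A `ppca_model`.
#' @param data A [spectral_dataset()] (or matrix) with matching `p`.
#' @return The log-likelihood (scalar).
#' @export
ppca_loglik <- function(model, data) {
  data <- as_spectral_dataset(data)
  X <- data$values
  if (ncol(X) != nrow(model$W))
    stop("data has ", ncol(X), " bins but the model expects ", nrow(model$W),
         call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  q <- model$q
  W <- model$W
  s2 <- model$sigma2
  Xc <- sweep(X, 2L, model$mu)
  M <- crossprod(W)
  diag(M) <- diag(M) + s2
  ch <- chol(M)
  Minv <- chol2inv(ch)
  XW <- Xc %*% W
  quad <- (sum(Xc^2) - sum((XW %*% Minv) * XW)) / s2
  -0.5 * (n * p * log(2 * pi) + n * ((p - q) * log(s2) + 2 * sum(log(diag(ch)))) +
            quad)
}

#' Latent posterior (scores with uncertainty)
#'
#' The posterior of the latent variable given an observation is
#' `N_q(M^{-1} W' (x - mu), sigma2 M^{-1})` with `M = W'W + sigma2 I`.
#' The posterior mean is the probabilistic analogue of a principal
#' component score; the shared posterior covariance quantifies its
#' uncertainty and is returned together with per-sample 2-D posterior
#' ellipses for plotting.
#'
#' @param model A `ppca_model`.
#' @param data A [spectral_dataset()] compatible with the model.
#' @param level Coverage level of the posterior ellipses, default 0.95.
#' @param dims Length-2 integer vector: which two components the ellipses
#'   describe (default the first two; ignored when `q = 1`).
#' @return An object of class `latent_posterior`: list with `means`
#'   (n x q), `covariance` (q x q, shared across samples), `level` and
#'   `ellipse` (data frame of centres, semi-axes and angle, or `NULL`
#'   when `q = 1`).
#' @export
posterior_latent <- function(model, data, level = 0.95, dims = c(1L, 2L)) {
  data <- as_spectral_dataset(data)
  stopifnot(level > 0, level < 1)
  X <- data$values
  if (ncol(X) != nrow(model$W))
    stop("data/model dimension mismatch", call. = FALSE)
  W <- model$W
  q <- model$q
  M <- crossprod(W)
  diag(M) <- diag(M) + model$sigma2
  Minv <- tryCatch(chol2inv(chol(M)), error = function(e)
    stop("M = W'W + sigma2 I is not invertible (degenerate model)", call. = FALSE))
  means <- sweep(X, 2L, model$mu) %*% W %*% Minv
  covv <- model$sigma2 * Minv
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

#' @export
print.latent_posterior <- function(x, ...) {
  cat(sprintf("Latent posterior: %d samples x %d components (%.0f%% ellipses)\n",
              nrow(x$means), ncol(x$means), 100 * x$level))
  invisible(x)
}

#' Align a loadings matrix with a reference
#'
#' PPCA loadings are identified only up to an orthogonal rotation (and
#' per-column sign). Alignment is required before comparing loadings from
#' different fits, e.g. each jackknife leave-one-out refit against the
#' full-data fit. `"procrustes"` finds the orthogonal `Q` minimising
#' `||W Q - reference||_F`; `"sign"` restricts `Q` to per-column sign
#' flips.
#'
#' @param W p x q matrix to align.
#' @param reference p x q reference matrix.
#' @param method `"procrustes"` or `"sign"`.
#' @return The aligned matrix `W %*% Q`, with the orthogonal `Q` attached
#'   as attribute `"rotation"`.
#' @export
align_loadings <- function(W, reference, method = c("procrustes", "sign")) {
  method <- match.arg(method)
  W <- as.matrix(W)
  reference <- as.matrix(reference)
  if (!all(dim(W) == dim(reference)))
    stop("'W' and 'reference' must have identical dimensions", call. = FALSE)
  q <- ncol(W)
  if (method == "procrustes") {
    A <- crossprod(W, reference)
    sv <- svd(A)
    if (min(sv$d) <= max(sv$d[1L], 0) * 1e-12) {
      warning("rank-deficient cross-product; falling back to sign matching")
      return(align_loadings(W, reference, method = "sign"))
    }
    Q <- sv$u %*% t(sv$v)
  } else {
    s <- vapply(seq_len(q), function(k) {
      cp <- sum(W[, k] * reference[, k])
      if (cp < 0) -1 else 1
    }, numeric(1))
    Q <- diag(s, q, q)
  }
  out <- W %*% Q
  dimnames(out) <- dimnames(reference)
  attr(out, "rotation") <- Q
  out
}
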