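#' Mixture of PPCA models
#'
#' An `mppca_model` holds a G-component finite mixture in which component
#' g is a PPCA model with its own loadings `W[[g]]` and mean `mu[g, ]`,
#' while the isotropic noise variance `sigma2` is shared by all groups
#' for parsimony. Component covariances are
#' `Sigma_g = W_g W_g' + sigma2 I`.
#'
#' @param pi Mixing proportions (length G, non-negative, summing to 1).
#' @param W List of G loadings matrices, each p x q.
#' @param mu G x p matrix of component means.
#' @param sigma2 Shared noise variance.
#' @return An object of class `mppca_model`.
#' @keywords internal
mppca_model <- function(pi, W, mu, sigma2) {
  G <- length(pi)
  stopifnot(is.list(W), length(W) == G, nrow(mu) == G,
            abs(sum(pi) - 1) < 1e-8, all(pi >= 0), sigma2 >= 0)
  q <- ncol(W[[1L]])
  structure(list(G = G, pi = as.numeric(pi), W = W, mu = mu,
                 sigma2 = sigma2, q = q), class = "mppca_model")
}

#' @export
print.mppca_model <- function(x, ...) {
  cat(sprintf("MPPCA model: G = %d groups, p = %d bins, q = %d components, shared sigma2 = %.4g\n",
              x$G, ncol(x$mu), x$q, x$sigma2))
  cat("  mixing proportions:", paste(sprintf("%.3f", x$pi), collapse = ", "), "\n")
  invisible(x)
}

# Per-sample log density of one PPCA mixture component, via the
# Woodbury/determinant-lemma forms (no p x p matrices).
component_logdens <- function(X, mu_g, W, s2) {
  p <- ncol(X)
  q <- ncol(W)
  Xc <- sweep(X, 2L, mu_g)
  M <- crossprod(W)
  diag(M) <- diag(M) + s2
  ch <- chol(M)
  Minv <- chol2inv(ch)
  XW <- Xc %*% W
  quad <- (rowSums(Xc^2) - rowSums((XW %*% Minv) * XW)) / s2
  -0.5 * (p * log(2 * pi) + (p - q) * log(s2) + 2 * sum(log(diag(ch))) + quad)
}

# Responsibilities + mixture log-likelihood from raw parameters.
mixture_posterior <- function(X, pi, mu, Wl, s2) {
  G <- length(pi)
  ld <- vapply(seq_len(G), function(g)
    component_logdens(X, mu[g, ], Wl[[g]], s2), numeric(nrow(X)))
  if (G == 1L) ld <- matrix(ld, ncol = 1L)
  lp <- sweep(ld, 2L, log(pi), "+")
  m <- apply(lp, 1L, max)
  ez <- exp(lp - m)
  tot <- rowSums(ez)
  list(z = ez / tot, loglik = sum(m + log(tot)))
}

#' MPPCA mixture log-likelihood
#'
#' Sum over samples of the log mixture density
#' `sum_g pi_g N_p(x; mu_g, W_g W_g' + sigma2 I)`, evaluated by
#' log-sum-exp so well-separated components cannot underflow.
#'
#' @param model An `mppca_model`.
#' @param data A [spectral_dataset()].
#' @return The log-likelihood (scalar).
#' @export
mixture_loglik <- function(model, data) {
  data <- as_spectral_dataset(data)
  if (ncol(data$values) != ncol(model$mu))
    stop("data/model dimension mismatch", call. = FALSE)
  mixture_posterior(data$values, model$pi, model$mu, model$W,
                    model$sigma2)$loglik
}

#' Posterior group-membership probabilities
#'
#' Bayes-rule responsibilities `z_ig` of each sample for each mixture
#' component, with hard cluster labels by maximum a posteriori assignment
#' (ties broken toward the lowest group index).
#'
#' @param model An `mppca_model`.
#' @param data A [spectral_dataset()].
#' @return An object of class `responsibilities`: list with `z_hat`
#'   (n x G, rows summing to 1) and `labels` (n integer assignments).
#' @export
responsibilities <- function(model, data) {
  data <- as_spectral_dataset(data)
  if (ncol(data$values) != ncol(model$mu))
    stop("data/model dimension mismatch", call. = FALSE)
  z <- mixture_posterior(data$values, model$pi, model$mu, model$W,
                         model$sigma2)$z
  rownames(z) <- data$sample_ids
  colnames(z) <- paste0("group", seq_len(model$G))
  structure(list(z_hat = z, labels = max.col(z, ties.method = "first")),
            class = "responsibilities")
}

#' @export
print.responsibilities <- function(x, ...) {
  cat(sprintf("Responsibilities: %d samples x %d groups; cluster sizes: %s\n",
              nrow(x$z_hat), ncol(x$z_hat),
              paste(tabulate(x$labels, ncol(x$z_hat)), collapse = "/")))
  invisible(x)
}

# One AECM run from a given initial partition. First cycle: E-step on
# group membership, then CM of (pi, mu_g); second cycle: E-step again
# (membership + latent moments), then CM of (W_g, shared sigma2).
# Returns status "empty" if a component's expected size falls below 2
# (its loadings would be unestimable).
mppca_aecm <- function(X, q, G, z0, Wl, s2, max_iter, tol,
                       map = FALSE, prior = NULL, floor = 1e-10) {
  n <- nrow(X)
  p <- ncol(X)
  Iq <- diag(q)
  z <- z0
  floored <- FALSE
  s2 <- max(s2, floor)
  ll_trace <- numeric(0)
  obj_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  pi <- colSums(z) / n
  mu <- (t(z) %*% X) / colSums(z)
  repeat {
    if (iter > 0L) {
      # AECM cycle 1 E-step
      z <- mixture_posterior(X, pi, mu, Wl, s2)$z
    }
    ng <- colSums(z)
    if (any(ng < 2)) return(list(status = "empty"))
    # CM 1: mixing proportions and means
    pi <- ng / n
    mu <- (t(z) %*% X) / ng
    # cycle 2 E-step with updated (pi, mu)
    z <- mixture_posterior(X, pi, mu, Wl, s2)$z
    ng <- colSums(z)
    if (any(ng < 2)) return(list(status = "empty"))
    # CM 2: loadings and the shared noise variance
    s2acc <- 0
    for (g in seq_len(G)) {
      Xcg <- sweep(X, 2L, mu[g, ])
      Wg <- Wl[[g]]
      XW <- Xcg %*% Wg
      SW <- crossprod(Xcg, z[, g] * XW) / ng[g]
      Mg <- crossprod(Wg)
      diag(Mg) <- diag(Mg) + s2
      Minv <- chol2inv(chol(Mg))
      WtSW <- crossprod(Wg, SW)
      Wnew <- SW %*% solve(s2 * Iq + Minv %*% WtSW)
      trSg <- sum(z[, g] * Xcg^2) / ng[g]
      s2acc <- s2acc + ng[g] / n * (trSg - sum((SW %*% Minv) * Wnew))
      Wl[[g]] <- Wnew
    }
    s2_ml <- s2acc / p
    s2 <- if (map)
      (n * p * s2_ml / 2 + prior$scale) / (n * p / 2 + prior$shape + 1)
    else s2_ml
    if (!is.finite(s2) || s2 < floor) {
      s2 <- floor
      floored <- TRUE
      iter <- iter + 1L
      if (length(ll_trace) == 0L)
        ll_trace <- mixture_posterior(X, pi, mu, Wl, s2)$loglik
      break
    }
    ll <- mixture_posterior(X, pi, mu, Wl, s2)$loglik
    ll_trace <- c(ll_trace, ll)
    obj_trace <- c(obj_trace, if (map) ll + log_invgamma(s2, prior) else ll)
    iter <- iter + 1L
    if (aitken_converged(obj_trace, tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  list(status = "ok", pi = pi, mu = mu, W = Wl, sigma2 = s2,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged, n_iter = iter, sigma2_floor = floored)
}

# Hard partition -> indicator matrix.
partition_to_z <- function(labels, G) {
  z <- matrix(0, length(labels), G)
  z[cbind(seq_along(labels), labels)] <- 1
  z
}

#' Fit a mixture of PPCA models by the AECM algorithm
#'
#' Simultaneous clustering and per-group dimension reduction. Fitting
#' alternates two EM cycles: the first conditions on group membership and
#' updates the mixing proportions and group means; the second adds the
#' latent component scores and updates the group loadings and the shared
#' noise variance. The observed-data mixture log-likelihood is
#' non-decreasing across cycles and convergence is assessed by Aitken's
#' acceleration. Multiple starts guard against local optima: the first
#' start initialises the partition by k-means on the spectra, the rest by
#' random partitions; a start whose components collapse below 2 expected
#' members is discarded and replaced.
#'
#' @inheritParams fit_ppca
#' @param G Number of mixture components (groups), `G >= 1`.
#' @param n_starts Number of initialisations (default 10).
#' @param init `"kmeans"` (default; first start) or `"random"` (all
#'   starts random partitions).
#' @param max_iter Maximum AECM iterations per start (default 500).
#' @return An object of class `mppca_fit`: as [fit_ppca()] plus the
#'   fitted `mppca_model`, final `responsibilities`, hard `labels`, `G`
#'   and `n_failed_starts`.
#' @seealso [responsibilities()], [cross_tabulate()], [select_model()]
#' @export
fit_mppca <- function(data, q, G, n_starts = 10, max_iter = 500, tol = 1e-4,
                      init = c("kmeans", "random"), seed = NULL, prior = NULL,
                      sigma2_floor = 1e-10) {
  data <- as_spectral_dataset(data)
  init <- match.arg(init)
  X <- data$values
  n <- nrow(X)
  p <- ncol(X)
  check_q(q, n, p)
  if (G < 1L) stop("G must be at least 1", call. = FALSE)
  if (n < 2L * G)
    stop("need at least 2 samples per prospective group", call. = FALSE)
  sp <- sample_cov_spectrum(X, q)
  if (is.null(prior)) prior <- default_sigma2_prior(sp$lambda)
  glob <- init_ppca(X, q, "eigen", NULL, sp, sigma2_floor)

  # Per-component starting values from a hard partition: each group gets
  # loadings from its own covariance (global directions would point along
  # the between-group axes and let a component swallow its neighbours'
  # means in the first E-step), and sigma2 starts at the pooled
  # within-group residual scale.
  init_from_partition <- function(labels) {
    Wl <- vector("list", G)
    s2s <- numeric(G)
    for (g in seq_len(G)) {
      Xg <- X[labels == g, , drop = FALSE]
      if (nrow(Xg) >= q + 2L) {
        spg <- sample_cov_spectrum(Xg, q)
        s2g <- mean(spg$lambda[(q + 1L):p])
        scale <- sqrt(pmax(spg$lambda[seq_len(q)] - s2g, 0))
        Wl[[g]] <- sweep(spg$vectors, 2L, scale, "*")
        s2s[g] <- s2g
      } else {
        vbar <- mean(apply(Xg, 2L, stats::var))
        if (!is.finite(vbar) || vbar <= 0) vbar <- glob$s0
        Wl[[g]] <- matrix(stats::rnorm(p * q, sd = sqrt(vbar / q)), p, q)
        s2s[g] <- vbar
      }
    }
    list(W = Wl, s0 = max(mean(s2s), sigma2_floor))
  }

  run_starts <- function() {
    best <- NULL
    failed <- 0L
    n_try <- if (G == 1L) 1L else n_starts
    attempt <- 0L
    while (attempt < 2L * n_try && (attempt < n_try || is.null(best))) {
      attempt <- attempt + 1L
      labels <- if (G == 1L) {
        rep(1L, n)
      } else if (init == "kmeans" && attempt == 1L) {
        km <- tryCatch(stats::kmeans(X, centers = G, nstart = 5L),
                       error = function(e) NULL)
        if (is.null(km)) sample(rep_len(seq_len(G), n)) else km$cluster
      } else {
        sample(rep_len(seq_len(G), n))
      }
      ini <- init_from_partition(labels)
      res <- mppca_aecm(X, q, G, partition_to_z(labels, G), ini$W, ini$s0,
                        max_iter, tol, map = FALSE, floor = sigma2_floor)
      if (res$status != "ok") {
        failed <- failed + 1L
        next
      }
      if (is.null(best) || res$loglik > best$loglik) best <- res
    }
    if (is.null(best))
      stop("all MPPCA starts collapsed to an empty component; try smaller G",
           call. = FALSE)
    best$n_failed_starts <- failed
    best
  }
  ml <- with_seed(seed, run_starts())

  # MAP-sigma2 refit warm-started from the ML solution
  z_ml <- mixture_posterior(X, ml$pi, ml$mu, ml$W, max(ml$sigma2, sigma2_floor))$z
  mp <- mppca_aecm(X, q, G, z_ml, ml$W, ml$sigma2, max_iter, tol,
                   map = TRUE, prior = prior, floor = sigma2_floor)
  if (identical(mp$status, "empty")) mp <- ml  # degenerate fallback

  Wl <- lapply(ml$W, function(w) {
    w <- canonicalize_loadings(w)$W
    rownames(w) <- data$bin_labels
    w
  })
  rownames(ml$mu) <- paste0("group", seq_len(G))
  colnames(ml$mu) <- data$bin_labels
  model <- mppca_model(ml$pi, Wl, ml$mu, ml$sigma2)
  resp <- responsibilities(model, data)
  K <- count_params("mppca", p = p, q = q, G = G)
  structure(list(
    model = model,
    loglik = ml$loglik,
    loglik_trace = ml$loglik_trace,
    converged = ml$converged,
    n_iter = ml$n_iter,
    bic = bic(ml$loglik, K, n),
    modified_bic = bic(mp$loglik, K, n),
    prop_var = sum(sp$lambda[seq_len(q)]) / sum(sp$lambda),
    sigma2_floor = ml$sigma2_floor,
    responsibilities = resp,
    labels = resp$labels,
    n_failed_starts = ml$n_failed_starts,
    prior = prior, n = n, p = p, q = q, G = G, kind = "mppca"),
    class = "mppca_fit")
}

#' @export
print.mppca_fit <- function(x, ...) {
  cat(sprintf("MPPCA fit: n = %d, p = %d, q = %d, G = %d\n",
              x$n, x$p, x$q, x$G))
  cat(sprintf("  loglik %.3f after %d AECM iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  BIC %.2f | modified BIC %.2f | cluster sizes %s\n",
              x$bic, x$modified_bic,
              paste(tabulate(x$labels, x$G), collapse = "/")))
  invisible(x)
}

#' Cross-tabulate cluster labels against known classes
#'
#' Contingency table of estimated group memberships versus reference
#' classes, with the adjusted Rand index (ARI) as a summary of agreement
#' (1 = identical partitions, ~0 = chance).
#'
#' @param labels Estimated assignments (length n).
#' @param truth Reference classes (length n).
#' @return An object of class `cluster_xtab`: list with `table` and
#'   `ari`.
#' @export
cross_tabulate <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("'labels' and 'truth' must have the same length", call. = FALSE)
  structure(list(table = table(cluster = factor(labels),
                               truth = factor(truth)),
                 ari = mclust::adjustedRandIndex(labels, truth)),
            class = "cluster_xtab")
}

#' @export
print.cluster_xtab <- function(x, ...) {
  print(x$table)
  cat(sprintf("Adjusted Rand index: %.3f\n", x$ari))
  invisible(x)
}
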