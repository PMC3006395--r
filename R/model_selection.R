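#' Bayesian Information Criterion
#'
#' `BIC = 2 l - K log(n)` with `l` the maximum log-likelihood, `K` the
#' number of free parameters and `n` the number of observations. Higher
#' values indicate a preferable model.
#'
#' @param loglik Maximised log-likelihood.
#' @param K Number of free parameters (`K >= 0`).
#' @param n Number of observations (`n >= 1`).
#' @return The criterion value (scalar; higher is better).
#' @export
bic <- function(loglik, K, n) {
  stopifnot(is.finite(K), K >= 0, is.finite(n), n >= 1)
  2 * loglik - K * log(n)
}

#' Free-parameter counts for the fitted models
#'
#' Counts raw parameters: loadings (`p * q` per group), means (`p` per
#' group), one shared noise variance, mixing proportions (`G - 1`) and,
#' for the covariate model, the `q * (L + 1)` regression matrix. With
#' `convention = "rotation-corrected"` the `q (q - 1) / 2` parameters
#' absorbed by the rotational non-identifiability of each loadings matrix
#' are subtracted; component selection can differ between the two
#' conventions, so both are exposed.
#'
#' @param kind One of `"ppca"`, `"ppcca"`, `"mppca"`.
#' @param p Number of spectral bins.
#' @param q Number of principal components.
#' @param L Number of covariates (PPCCA only).
#' @param G Number of mixture components (MPPCA only).
#' @param convention `"raw"` (default) or `"rotation-corrected"`.
#' @return Integer parameter count.
#' @export
count_params <- function(kind = c("ppca", "ppcca", "mppca"), p, q, L = 0L,
                         G = 1L, convention = c("raw", "rotation-corrected")) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  stopifnot(p >= 1, q >= 1, L >= 0, G >= 1)
  corr <- if (convention == "rotation-corrected") q * (q - 1) / 2 else 0
  K <- switch(kind,
    ppca = p * q + p + 1 - corr,
    ppcca = p * q + p + 1 + q * (L + 1) - corr,
    mppca = (G - 1) + G * (p * q + p - corr) + 1)
  as.integer(K)
}

#' Inverse-gamma prior on the noise variance
#'
#' Conjugate prior used to compute the MAP estimate of `sigma2` inside
#' the EM algorithm; the BIC evaluated at that MAP estimate (the
#' "modified BIC") avoids the likelihood singularities that make the
#' plain criterion unstable when `n` is much smaller than `p`.
#'
#' @param shape Shape parameter, must exceed 1 (finite prior mean).
#' @param scale Scale parameter, positive. The prior mode is
#'   `scale / (shape + 1)`.
#' @return An object of class `sigma2_prior`.
#' @export
sigma2_prior <- function(shape = 3, scale = 1) {
  stopifnot(is.finite(shape), shape > 1, is.finite(scale), scale > 0)
  structure(list(shape = shape, scale = scale), class = "sigma2_prior")
}

# Default weakly-informative prior: shape 3 and scale 2 * vbar, where
# vbar is the mean per-bin sample variance, putting the prior mode at
# half the average variance scale of the data.
default_sigma2_prior <- function(lambda) {
  sigma2_prior(shape = 3, scale = 2 * max(mean(lambda), .Machine$double.eps))
}

#' @export
print.sigma2_prior <- function(x, ...) {
  cat(sprintf("Inverse-gamma sigma2 prior: shape %.3g, scale %.3g (mode %.3g)\n",
              x$shape, x$scale, x$scale / (x$shape + 1)))
  invisible(x)
}

#' Modified (MAP-regularised) BIC for a single model
#'
#' Refits the requested model with the `sigma2` M-step replaced by the
#' posterior mode under the inverse-gamma prior,
#' `sigma2_MAP = (RSS/2 + scale) / (n p / 2 + shape + 1)` with `RSS` the
#' expected residual sum of squares from the E-step, and returns
#' `2 l(theta_MAP) - K log(n)`. Finite even on data where the unpenalised
#' fit collapses onto the `sigma2 = 0` singularity.
#'
#' @param data A [spectral_dataset()].
#' @param kind `"ppca"`, `"ppcca"` or `"mppca"`.
#' @param q Number of principal components.
#' @param G Number of groups (MPPCA).
#' @param covs A [covariate_table()] (PPCCA).
#' @param prior A [sigma2_prior()]; defaults as in [fit_ppca()].
#' @param ... Further fitting options passed to the `fit_*` function.
#' @return The modified BIC value (scalar).
#' @export
modified_bic <- function(data, kind = c("ppca", "ppcca", "mppca"), q, G = 1L,
                         covs = NULL, prior = NULL, ...) {
  kind <- match.arg(kind)
  fit <- switch(kind,
    ppca = fit_ppca(data, q = q, prior = prior, ...),
    ppcca = fit_ppcca(data, covs = covs, q = q, prior = prior, ...),
    mppca = fit_mppca(data, q = q, G = G, prior = prior, ...))
  fit$modified_bic
}

#' Proportion of variance explained by the leading components
#'
#' Ratio of the sum of the q leading sample-covariance eigenvalues to the
#' total, matching conventional PCA reporting. A model-based alternative
#' `tr(WW') / (tr(WW') + p sigma2)` is available by supplying a fitted
#' model.
#'
#' @param data A [spectral_dataset()].
#' @param q Number of leading components.
#' @param model Optional `ppca_model`; when given, the model-based
#'   proportion is returned instead and `q` is taken from the model.
#' @return Proportion in `[0, 1]`.
#' @export
proportion_variance <- function(data, q, model = NULL) {
  if (!is.null(model)) {
    tw <- sum(model$W^2)
    return(tw / (tw + nrow(model$W) * model$sigma2))
  }
  data <- as_spectral_dataset(data)
  sp <- sample_cov_spectrum(data$values)
  lambda <- pmax(sp$lambda, 0)
  lambda[lambda < max(lambda) * 1e-12] <- 0
  if (q > sum(lambda > 0))
    stop("q exceeds the number of positive sample-covariance eigenvalues",
         call. = FALSE)
  sum(lambda[seq_len(q)]) / sum(lambda)
}

#' Model-grid search over q (and G) by modified BIC
#'
#' Fits one model per grid cell and tabulates log-likelihood, parameter
#' count, BIC, modified BIC and proportion of variance. The best model is
#' flagged by the highest modified BIC (ties broken by the smaller model,
#' i.e. earlier row). Per-cell failures are recorded as non-converged
#' rows with `NA` criteria rather than aborting the search.
#'
#' @param data A [spectral_dataset()].
#' @param kind `"ppca"`, `"ppcca"` or `"mppca"`.
#' @param q_range Integer vector of latent dimensions to try.
#' @param G_range Integer vector of group numbers (MPPCA; default 1).
#' @param covs A [covariate_table()] (PPCCA).
#' @param prior A [sigma2_prior()] shared across cells (default: derived
#'   from the data as in [fit_ppca()]).
#' @param seed Base seed; cell j uses `seed + j` so the search is
#'   deterministic given `(data, seed, ranges)`.
#' @param ... Further options for the `fit_*` functions.
#' @return A data frame of class `selection_table` with columns
#'   `model_kind, q, G, loglik, K, bic, modified_bic, prop_var, converged,
#'   best_bic, best_modified`.
#' @export
select_model <- function(data, kind = c("ppca", "ppcca", "mppca"), q_range,
                         G_range = 1L, covs = NULL, prior = NULL, seed = NULL,
                         ...) {
  kind <- match.arg(kind)
  data <- as_spectral_dataset(data)
  stopifnot(length(q_range) >= 1L, length(G_range) >= 1L)
  if (kind != "mppca" && !identical(as.integer(G_range), 1L))
    stop("G_range is only meaningful for kind = 'mppca'", call. = FALSE)
  grid <- expand.grid(q = as.integer(q_range), G = as.integer(G_range))
  rows <- vector("list", nrow(grid))
  for (j in seq_len(nrow(grid))) {
    qj <- grid$q[j]
    Gj <- grid$G[j]
    seed_j <- if (is.null(seed)) NULL else seed + j
    fit <- tryCatch(switch(kind,
      ppca = fit_ppca(data, q = qj, prior = prior, seed = seed_j, ...),
      ppcca = fit_ppcca(data, covs = covs, q = qj, prior = prior,
                        seed = seed_j, ...),
      mppca = fit_mppca(data, q = qj, G = Gj, prior = prior, seed = seed_j,
                        ...)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[j]] <- data.frame(model_kind = kind, q = qj, G = Gj, loglik = NA,
                              K = NA, bic = NA, modified_bic = NA,
                              prop_var = NA, converged = FALSE,
                              message = conditionMessage(fit))
    } else {
      K <- switch(kind,
        ppca = count_params("ppca", p = fit$p, q = qj),
        ppcca = count_params("ppcca", p = fit$p, q = qj, L = fit$L),
        mppca = count_params("mppca", p = fit$p, q = qj, G = Gj))
      rows[[j]] <- data.frame(model_kind = kind, q = qj, G = Gj,
                              loglik = fit$loglik, K = K, bic = fit$bic,
                              modified_bic = fit$modified_bic,
                              prop_var = fit$prop_var,
                              converged = fit$converged, message = "")
    }
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$modified_bic)))
    stop("every fit in the model grid failed; first message: ",
         tab$message[1L], call. = FALSE)
  tab$best_bic <- seq_len(nrow(tab)) == which.max(tab$bic)
  tab$best_modified <- seq_len(nrow(tab)) == which.max(tab$modified_bic)
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' @export
print.selection_table <- function(x, ...) {
  need <- c("model_kind", "q", "G", "modified_bic", "best_modified")
  if (!all(need %in% names(x))) return(NextMethod())
  cat("Model selection table (higher modified BIC is better):\n")
  df <- as.data.frame(x)
  df$message <- NULL
  print(format(df, digits = 5), ...)
  best <- df[x$best_modified, , drop = FALSE]
  if (nrow(best) == 1L)
    cat(sprintf("Best by modified BIC: %s with q = %d%s\n", best$model_kind,
                best$q, if (identical(best$model_kind, "mppca"))
                  sprintf(", G = %d", best$G) else ""))
  invisible(x)
}
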