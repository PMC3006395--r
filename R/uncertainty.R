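#' Jackknife standard error of a leave-one-out statistic
#'
#' For the n leave-one-out values `v_i` of a statistic,
#' `SE = sqrt((n - 1)/n * sum_i (v_i - vbar)^2)` with `vbar` their mean.
#' With n = 2 this reduces to `|v_1 - v_2| / 2`.
#'
#' @param values Numeric vector of n >= 2 leave-one-out estimates.
#' @return The jackknife standard error (scalar, >= 0).
#' @export
jackknife_se <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("at least 2 leave-one-out values are required", call. = FALSE)
  if (!all(is.finite(values))) stop("leave-one-out values must be finite",
                                    call. = FALSE)
  sqrt((n - 1) / n * sum((values - mean(values))^2))
}

# Entrywise jackknife SEs for a stack of matrices stored as columns of a
# (p*q) x m matrix.
jackknife_se_matrix <- function(stack) {
  m <- ncol(stack)
  ctr <- stack - rowMeans(stack)
  sqrt((m - 1) / m * rowSums(ctr^2))
}

#' Jackknife standard errors and CIs for a fitted model
#'
#' Refits the model n times, leaving each sample out in turn, with every
#' refit warm-started at the full-data estimates (which cuts the cost of
#' the n EM runs dramatically). Each leave-one-out loadings matrix is
#' aligned to the full-data loadings before the standard errors are
#' computed -- loadings are identified only up to column sign (and
#' rotation), and standard errors are meaningless without this
#' alignment. Confidence intervals are `estimate +/- z * SE` by default
#' (`z` the normal quantile at `conf`); `ci = "t"` uses a t quantile on
#' n - 1 degrees of freedom instead. For a PPCCA fit the covariate
#' regression matrix `alpha` receives the identical treatment.
#'
#' @param fit A `ppca_fit` or `ppcca_fit` from [fit_ppca()] /
#'   [fit_ppcca()], fitted on `data`.
#' @param data The [spectral_dataset()] the model was fitted to.
#' @param covs The [covariate_table()] used for a PPCCA fit.
#' @param conf Confidence level (default 0.95).
#' @param align `"sign"` (default) or `"procrustes"` alignment of each
#'   leave-one-out fit to the full-data loadings.
#' @param ci `"normal"` (default) or `"t"` interval construction.
#' @param tol,max_iter EM control for the leave-one-out refits; the
#'   default tolerance is tighter than the fitting default because the
#'   warm starts make refits cheap.
#' @return An object of class `jackknife_result`: matrices `estimate`,
#'   `se`, `ci_low`, `ci_high`, `significant` (CI excludes zero) for the
#'   loadings; the corresponding `alpha_*` matrices for a PPCCA fit;
#'   `n_refits`, `n_excluded`, `conf`, `align`.
#' @seealso [significant_loadings()], [jackknife_se()]
#' @export
jackknife_loadings <- function(fit, data, covs = NULL, conf = 0.95,
                               align = c("sign", "procrustes"),
                               ci = c("normal", "t"),
                               tol = 1e-6, max_iter = 2000) {
  align <- match.arg(align)
  ci <- match.arg(ci)
  data <- as_spectral_dataset(data)
  X <- data$values
  n <- nrow(X)
  if (n < 3L) stop("jackknife needs at least 3 samples", call. = FALSE)
  if (!inherits(fit, c("ppca_fit", "ppcca_fit")))
    stop("'fit' must be a ppca_fit or ppcca_fit", call. = FALSE)
  if (!isTRUE(fit$converged))
    warning("full-data fit had not converged; jackknife SEs may be unreliable")
  is_ppcca <- inherits(fit, "ppcca_fit")
  model <- fit$model
  W_full <- model$W
  p <- nrow(W_full)
  q <- ncol(W_full)
  if (is_ppcca) {
    if (is.null(covs)) covs <- fit$covariates
    des <- covs$design
    if (nrow(des) != n)
      stop("covariate rows do not match the number of samples", call. = FALSE)
  }

  W_stack <- matrix(NA_real_, p * q, n)
  if (is_ppcca) A_stack <- matrix(NA_real_, length(model$alpha), n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    if (is_ppcca) {
      ri <- ppcca_em_engine(Xi, des[-i, , drop = FALSE], q, W_full,
                            model$alpha, model$sigma2, max_iter, tol)
    } else {
      # the PPCA leave-one-out MLE is available in closed form, which is
      # both exact and far faster than travelling there by warm-started
      # EM; the engine run from the eigen start confirms convergence
      spi <- sample_cov_spectrum(Xi, q)
      inii <- init_ppca(Xi, q, "eigen", NULL, spi, 1e-10)
      ri <- ppca_em_engine(Xi, q, inii$W0, inii$s0, max_iter, tol)
    }
    ok[i] <- ri$converged && !ri$sigma2_floor
    if (!ok[i]) next
    # apply the same canonicalisation as the full fit, so each
    # leave-one-out value is the estimator's actual output for that
    # subsample (the canonical basis itself wobbles with the removed
    # sample, and that wobble is part of the loading uncertainty)
    if (is_ppcca) {
      cn <- canonicalize_ppcca(ri$W, ri$alpha)
      Wa <- align_loadings(cn$W, W_full, method = align)
      A_stack[, i] <- crossprod(attr(Wa, "rotation"), cn$alpha)
    } else {
      Wa <- align_loadings(canonicalize_loadings(ri$W)$W, W_full,
                           method = align)
    }
    W_stack[, i] <- Wa
  }
  n_bad <- sum(!ok)
  if (n_bad > 0.05 * n)
    stop(sprintf("%d of %d leave-one-out refits failed to converge", n_bad, n),
         call. = FALSE)
  if (n_bad > 0)
    warning(sprintf("%d leave-one-out refit(s) excluded (non-convergence)",
                    n_bad))
  m <- sum(ok)
  crit <- if (ci == "normal") stats::qnorm((1 + conf) / 2)
          else stats::qt((1 + conf) / 2, df = m - 1)

  se <- matrix(jackknife_se_matrix(W_stack[, ok, drop = FALSE]), p, q,
               dimnames = dimnames(W_full))
  ci_low <- W_full - crit * se
  ci_high <- W_full + crit * se
  out <- list(estimate = W_full, se = se, ci_low = ci_low, ci_high = ci_high,
              significant = ci_low > 0 | ci_high < 0,
              n_refits = m, n_excluded = n_bad, conf = conf, align = align,
              bin_labels = data$bin_labels)
  if (is_ppcca) {
    a_se <- matrix(jackknife_se_matrix(A_stack[, ok, drop = FALSE]),
                   q, ncol(model$alpha), dimnames = dimnames(model$alpha))
    out$alpha_estimate <- model$alpha
    out$alpha_se <- a_se
    out$alpha_ci_low <- model$alpha - crit * a_se
    out$alpha_ci_high <- model$alpha + crit * a_se
    out$alpha_significant <- out$alpha_ci_low > 0 | out$alpha_ci_high < 0
  }
  structure(out, class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("Jackknife result: %d refits (%d excluded), %.0f%% CIs, %s alignment\n",
              x$n_refits, x$n_excluded, 100 * x$conf, x$align))
  cat(sprintf("  %d of %d loadings on PC1 significantly different from zero\n",
              sum(x$significant[, 1L]), nrow(x$significant)))
  if (!is.null(x$alpha_estimate)) {
    cat("Covariate effects (estimate [CI]):\n")
    a <- x$alpha_estimate
    for (k in seq_len(nrow(a))) {
      cat(sprintf("  PC %d: %s\n", k, paste(sprintf(
        "%s %.2f (%.2f, %.2f)%s", colnames(a), a[k, ],
        x$alpha_ci_low[k, ], x$alpha_ci_high[k, ],
        ifelse(x$alpha_significant[k, ], "*", "")), collapse = "  ")))
    }
  }
  invisible(x)
}

#' Select spectral bins with significant, large loadings
#'
#' Bins whose loading CI on the chosen component excludes zero and whose
#' absolute loading exceeds `cutoff`, ordered by decreasing absolute
#' loading. With `cutoff = 0` this is the set of all significant bins on
#' the component; raising the cutoff sparsifies the marker list.
#'
#' @param jk A [jackknife_loadings()] result.
#' @param pc Which principal component, `1 <= pc <= q`.
#' @param cutoff Minimum absolute loading (default 0).
#' @return Data frame with columns `bin_label`, `loading`, `se`,
#'   `ci_low`, `ci_high`, sorted by `abs(loading)` descending.
#' @export
significant_loadings <- function(jk, pc = 1L, cutoff = 0) {
  stopifnot(inherits(jk, "jackknife_result"), cutoff >= 0)
  q <- ncol(jk$estimate)
  if (pc < 1L || pc > q)
    stop("pc must be between 1 and ", q, call. = FALSE)
  w <- jk$estimate[, pc]
  keep <- jk$significant[, pc] & abs(w) > cutoff
  out <- data.frame(bin_label = jk$bin_labels, loading = w,
                    se = jk$se[, pc], ci_low = jk$ci_low[, pc],
                    ci_high = jk$ci_high[, pc],
                    row.names = NULL, stringsAsFactors = FALSE)[keep, ]
  out[order(abs(out$loading), decreasing = TRUE), , drop = FALSE]
}

#' Frequency diagnostics for choosing a loading cutoff
#'
#' Histogram of the absolute loadings of the significant bins on one
#' component, together with the number of bins retained as the cutoff
#' threshold increases. A region where the retained count drops steeply
#' while the loading values stay roughly constant suggests a cutoff; no
#' cutoff is chosen automatically -- the choice is the analyst's.
#'
#' @param loadings Numeric vector of loadings for one component (all p
#'   bins).
#' @param significant Logical vector flagging the significant bins.
#' @param n_bins Number of histogram bins (default 20, must be >= 2).
#' @return An object of class `cutoff_frequency`: list with `histogram`
#'   (data frame of bin midpoints and counts) and `retained` (data frame
#'   of thresholds and the number of significant bins whose absolute
#'   loading exceeds each).
#' @export
cutoff_frequency <- function(loadings, significant, n_bins = 20L) {
  stopifnot(length(loadings) == length(significant), n_bins >= 2L)
  a <- abs(loadings[significant])
  if (length(a) == 0L) {
    warning("no significant bins; returning empty tables")
    return(structure(list(
      histogram = data.frame(mid = numeric(0), count = integer(0)),
      retained = data.frame(threshold = numeric(0), count = integer(0))),
      class = "cutoff_frequency"))
  }
  breaks <- seq(0, max(a) * (1 + 1e-8), length.out = n_bins + 1L)
  h <- hist(a, breaks = breaks, plot = FALSE)
  thresholds <- breaks[-length(breaks)]
  structure(list(
    histogram = data.frame(mid = h$mids, count = h$counts),
    retained = data.frame(threshold = thresholds,
                          count = vapply(thresholds,
                                         function(t) sum(a > t), integer(1)))),
    class = "cutoff_frequency")
}

#' @export
print.cutoff_frequency <- function(x, ...) {
  cat("Cutoff diagnostics over", sum(x$histogram$count), "significant bins\n")
  print(x$retained)
  invisible(x)
}

#' Per-bin two-group tests on selected spectral bins
#'
#' Welch two-sample t-test of each listed bin between the two groups,
#' with Benjamini-Hochberg adjustment across the listed bins. Typically
#' applied to the bins selected by [significant_loadings()] to ask which
#' of the structure-carrying bins actually differ between treatment
#' groups.
#'
#' @param data A [spectral_dataset()].
#' @param groups Two-level factor (or coercible) of length n; each group
#'   needs at least 2 samples.
#' @param bins Bins to test: integer indices or bin labels. Default all.
#' @param adjust Multiple-testing correction method for
#'   [stats::p.adjust()] (default `"BH"`).
#' @return Data frame with one row per tested bin: `bin_label`,
#'   group means, `t`, `df`, `p`, `p_adjusted` and `direction`
#'   (sign of second-level mean minus first-level mean).
#' @export
group_bin_tests <- function(data, groups, bins = NULL, adjust = "BH") {
  data <- as_spectral_dataset(data)
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly 2 levels", call. = FALSE)
  if (length(groups) != nrow(data$values))
    stop("'groups' length does not match the number of samples", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  if (is.null(bins)) {
    idx <- seq_along(data$bin_labels)
  } else if (is.character(bins)) {
    idx <- match(bins, data$bin_labels)
    if (anyNA(idx)) stop("unknown bin label: ", bins[is.na(idx)][1L],
                         call. = FALSE)
  } else {
    idx <- as.integer(bins)
    if (any(idx < 1L | idx > length(data$bin_labels)))
      stop("bin index out of range", call. = FALSE)
  }
  g1 <- groups == levels(groups)[1L]
  res <- lapply(idx, function(j) {
    x1 <- data$values[g1, j]
    x2 <- data$values[!g1, j]
    tt <- tryCatch(stats::t.test(x2, x1), error = function(e) NULL)
    if (is.null(tt)) {  # both groups essentially constant
      list(t = 0, df = NA_real_, p = if (mean(x2) == mean(x1)) 1 else 0)
    } else {
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
    }
  })
  out <- data.frame(
    bin_label = data$bin_labels[idx],
    mean_1 = colMeans(data$values[g1, idx, drop = FALSE]),
    mean_2 = colMeans(data$values[!g1, idx, drop = FALSE]),
    t = vapply(res, `[[`, numeric(1), "t"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p = vapply(res, `[[`, numeric(1), "p"),
    row.names = NULL, stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out$direction <- sign(out$mean_2 - out$mean_1)
  attr(out, "group_levels") <- levels(groups)
  out
}
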