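#' Construct a spectral dataset
#'
#' A `spectral_dataset` holds an n x p matrix of spectral-bin intensities
#' with rows as samples (spectra) and columns as bins. Bin labels are
#' conventionally the ppm centre of each integrated region (e.g. `"3.30"`).
#' All model-fitting functions in the package consume this container.
#'
#' @param values Numeric matrix, n samples by p bins. All entries must be
#'   finite; `n >= 2` and `p >= 2`.
#' @param sample_ids Character vector of n unique sample identifiers.
#'   Defaults to the rownames of `values`, or `S1..Sn`.
#' @param bin_labels Character vector of p unique bin labels. Defaults to
#'   the colnames of `values`, or `B1..Bp`.
#' @param preprocessing A list recording preprocessing already applied;
#'   normally left at its default and updated by [preprocess()].
#'
#' @return An object of class `spectral_dataset`: a list with elements
#'   `values`, `sample_ids`, `bin_labels` and `preprocessing`.
#' @seealso [read_spectra()], [preprocess()]
#' @export
spectral_dataset <- function(values, sample_ids = NULL, bin_labels = NULL,
                             preprocessing = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  n <- nrow(values)
  p <- ncol(values)
  if (n < 2L) stop("at least 2 samples (rows) are required", call. = FALSE)
  if (p < 2L) stop("at least 2 spectral bins (columns) are required", call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite intensity at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (is.null(bin_labels)) {
    bin_labels <- colnames(values)
    if (is.null(bin_labels)) bin_labels <- paste0("B", seq_len(p))
  }
  sample_ids <- as.character(sample_ids)
  bin_labels <- as.character(bin_labels)
  if (length(sample_ids) != n)
    stop("length of 'sample_ids' does not match number of rows", call. = FALSE)
  if (length(bin_labels) != p)
    stop("length of 'bin_labels' does not match number of columns", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID: ", sample_ids[duplicated(sample_ids)][1L],
         call. = FALSE)
  if (anyDuplicated(bin_labels))
    stop("duplicate bin label: ", bin_labels[duplicated(bin_labels)][1L],
         call. = FALSE)
  dimnames(values) <- list(sample_ids, bin_labels)
  if (is.null(preprocessing))
    preprocessing <- list(centered = FALSE, scaling = "none", normalized = FALSE)
  structure(list(values = values, sample_ids = sample_ids,
                 bin_labels = bin_labels, preprocessing = preprocessing),
            class = "spectral_dataset")
}

#' Coerce to a spectral dataset
#'
#' @param x A matrix, data frame or `spectral_dataset`.
#' @param ... Passed on to [spectral_dataset()].
#' @return A `spectral_dataset`.
#' @export
as_spectral_dataset <- function(x, ...) {
  if (inherits(x, "spectral_dataset")) return(x)
  spectral_dataset(as.matrix(x), ...)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$values)

#' @export
print.spectral_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Spectral dataset: %d samples x %d bins\n", d[1L], d[2L]))
  pp <- x$preprocessing
  cat(sprintf("  centered: %s, scaling: %s, normalized: %s\n",
              pp$centered, pp$scaling, pp$normalized))
  invisible(x)
}

# Row subsetting used by the jackknife; bypasses the n >= 2 check only
# for the validation already done on construction, not for new values.
subset_samples <- function(data, keep) {
  structure(list(values = data$values[keep, , drop = FALSE],
                 sample_ids = data$sample_ids[keep],
                 bin_labels = data$bin_labels,
                 preprocessing = data$preprocessing),
            class = "spectral_dataset")
}

#' Read a spectral-bin matrix from a delimited text file
#'
#' Expects a header row of bin labels, a first column of sample IDs and a
#' fully numeric body. Any non-numeric body cell (including `NA`) is an
#' error reported with its sample ID and bin label; nothing is silently
#' coerced or imputed.
#'
#' @param path Path to the file.
#' @param delimiter Field separator, default `","` (use `"\t"` for TSV).
#' @return A [spectral_dataset()].
#' @export
read_spectra <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop("expected a sample-ID column plus at least 2 bin columns", call. = FALSE)
  ids <- raw[[1L]]
  labels <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at sample '%s' (row %d), bin '%s' (column %d)",
                 body[bad[1L], bad[2L]], ids[bad[1L]], bad[1L],
                 labels[bad[2L]], bad[2L] + 1L), call. = FALSE)
  }
  spectral_dataset(num, sample_ids = ids, bin_labels = labels)
}

#' Write a spectral dataset to a delimited text file
#'
#' Values are written with 17 significant digits so that
#' `read_spectra(write_spectra(d))` round-trips doubles exactly.
#'
#' @param data A [spectral_dataset()].
#' @param path Output path.
#' @param delimiter Field separator, default `","`.
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(data, path, delimiter = ",") {
  data <- as_spectral_dataset(data)
  header <- paste(c("sample_id", data$bin_labels), collapse = delimiter)
  cells <- sprintf("%.17g", data$values)
  dim(cells) <- dim(data$values)
  rows <- vapply(seq_len(nrow(cells)), function(i)
    paste(c(data$sample_ids[i], cells[i, ]), collapse = delimiter), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Preprocess a spectral dataset
#'
#' Optionally row-normalises each spectrum to its total intensity, centres
#' each bin, and scales bins. Pareto scaling (dividing by the square root
#' of the standard deviation) is common metabolomics practice; it tempers,
#' rather than removes, the dominance of intense bins. The model mean
#' absorbs location, so the default is centring only.
#'
#' @param data A [spectral_dataset()].
#' @param center Subtract column (bin) means. Default `TRUE`.
#' @param scaling One of `"none"`, `"unit"` (divide by bin standard
#'   deviation) or `"pareto"` (divide by its square root).
#' @param normalize Divide each spectrum by its total intensity before
#'   any centring/scaling (off by default; appropriate only for positive
#'   raw intensities).
#' @return A new `spectral_dataset` with its preprocessing record updated.
#' @export
preprocess <- function(data, center = TRUE,
                       scaling = c("none", "unit", "pareto"),
                       normalize = FALSE) {
  data <- as_spectral_dataset(data)
  scaling <- match.arg(scaling)
  x <- data$values
  if (normalize) {
    tot <- rowSums(x)
    if (any(tot == 0)) stop("cannot normalize: a spectrum has zero total intensity",
                            call. = FALSE)
    x <- x / tot * mean(tot)
  }
  if (center) x <- sweep(x, 2L, colMeans(x))
  if (scaling != "none") {
    s <- apply(x, 2L, stats::sd)
    zero <- s <= .Machine$double.eps^0.5 * max(s, 1)
    if (any(zero))
      stop("zero-variance bin cannot be scaled: ", data$bin_labels[which(zero)[1L]],
           call. = FALSE)
    div <- if (scaling == "unit") s else sqrt(s)
    x <- sweep(x, 2L, div, "/")
  }
  pp <- data$preprocessing
  pp$centered <- pp$centered || center
  pp$scaling <- scaling
  pp$normalized <- pp$normalized || normalize
  spectral_dataset(x, data$sample_ids, data$bin_labels, preprocessing = pp)
}

#' Build a covariate table
#'
#' Packages subject covariates for the PPCCA model: stores the raw values,
#' a standardized copy (mean 0, unit sd by default) and the design matrix
#' with a leading intercept column. The centring/scaling used is recorded
#' so that new samples can be scored on the same scale.
#'
#' @param x Numeric vector, matrix or data frame of covariates
#'   (n rows, L covariates).
#' @param names Optional covariate names; defaults to colnames.
#' @param standardize Standardize each covariate to mean 0, sd 1
#'   (default `TRUE`). Covariate effect estimates are then per standard
#'   deviation of the covariate.
#' @param sample_ids Optional sample identifiers (for bookkeeping only).
#' @return An object of class `covariate_table` with elements `raw`,
#'   `names`, `standardized`, `design`, `scaling` and `sample_ids`.
#' @export
covariate_table <- function(x, names = NULL, standardize = TRUE,
                            sample_ids = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (!is.numeric(x)) stop("covariates must be numeric", call. = FALSE)
  if (!all(is.finite(x))) stop("covariates must be finite", call. = FALSE)
  n <- nrow(x)
  L <- ncol(x)
  if (n < 2L) stop("at least 2 samples are required", call. = FALSE)
  if (is.null(names)) {
    names <- colnames(x)
    if (is.null(names)) names <- paste0("covariate", seq_len(L))
  }
  colnames(x) <- names
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    if (any(scl == 0))
      stop("constant covariate cannot be standardized: ",
           names[which(scl == 0)[1L]], call. = FALSE)
    std <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  } else {
    ctr <- rep(0, L)
    scl <- rep(1, L)
    std <- x
  }
  design <- cbind(intercept = rep(1, n), std)
  structure(list(raw = x, names = names, standardized = std, design = design,
                 scaling = list(center = ctr, scale = scl,
                                standardized = standardize),
                 sample_ids = sample_ids),
            class = "covariate_table")
}

#' Read a covariate table from a delimited text file
#'
#' First column: sample IDs; header row: covariate names; body: numeric.
#'
#' @inheritParams read_spectra
#' @param standardize Passed to [covariate_table()].
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path, delimiter = ",", standardize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  body <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(body)) stop("non-numeric covariate value in ", path, call. = FALSE)
  covariate_table(body, standardize = standardize, sample_ids = ids)
}

# Empty covariate table (intercept-only design), the L = 0 PPCCA case.
intercept_only_covariates <- function(n) {
  structure(list(raw = matrix(numeric(0), n, 0), names = character(0),
                 standardized = matrix(numeric(0), n, 0),
                 design = cbind(intercept = rep(1, n)),
                 scaling = list(center = numeric(0), scale = numeric(0),
                                standardized = TRUE),
                 sample_ids = NULL),
            class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(sprintf("Covariate table: %d samples x %d covariates (%s)\n",
              nrow(x$design), length(x$names),
              if (x$scaling$standardized) "standardized" else "raw scale"))
  if (length(x$names)) cat("  ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}
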