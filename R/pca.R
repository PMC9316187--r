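#' Principal component analysis of averaged spectra
#'
#' Mean-centering only (no column autoscaling); loadings are the
#' eigenvectors of the centered covariance in decreasing eigenvalue order,
#' computed via [stats::prcomp()]. For a reproducible sign convention, each
#' loading is flipped so its largest-magnitude entry is positive.
#'
#' @param x Numeric matrix, samples in rows, wavelengths in columns.
#' @param rank Maximum number of components to retain (default: all).
#' @return A `libs_pca` object with elements `center` (mean spectrum),
#'   `loadings` (columns orthonormal), `sdev` (all singular values /
#'   sqrt(n-1)) and `explained_variance_ratio`.
#' @export
#' @examples
#' X <- matrix(rnorm(50), 10, 5)
#' p <- fit_pca(X)
#' glance(p)
fit_pca <- function(x, rank = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort("need at least 2 samples")
  if (!all(is.finite(x))) abort("non-finite values in data matrix")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  if (total_var == 0) abort("rank-0 matrix: no variance to decompose")
  keep <- seq_len(min(rank %||% ncol(pc$rotation), ncol(pc$rotation)))
  load <- pc$rotation[, keep, drop = FALSE]
  # sign convention: largest-|entry| of each loading is positive
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  structure(list(center = pc$center, loadings = load, sdev = pc$sdev,
                 explained_variance_ratio = pc$sdev^2 / total_var,
                 n_train = nrow(x)),
            class = "libs_pca")
}

#' Project samples onto a fitted PCA model
#'
#' Validation/new samples are always projected with the training-fitted
#' center and loadings; the model is never refit.
#'
#' @param model A `libs_pca` from [fit_pca()].
#' @param x Matrix (samples x wavelengths) on the same grid as the training
#'   data.
#' @param n_pcs Number of leading components to keep.
#' @return Score matrix (samples x `n_pcs`).
#' @export
project <- function(model, x, n_pcs = ncol(model$loadings)) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$center)) abort("wavelength grid mismatch with PCA model")
  if (n_pcs > ncol(model$loadings)) {
    abort(sprintf("n_pcs = %d exceeds available components (%d)",
                  n_pcs, ncol(model$loadings)))
  }
  sweep(x, 2, model$center, "-") %*% model$loadings[, seq_len(n_pcs), drop = FALSE]
}

#' @export
print.libs_pca <- function(x, ...) {
  cat("<libs_pca>\n")
  evr <- x$explained_variance_ratio
  cat(sprintf("  %d components retained; PC1-PC3 variance: %s\n",
              ncol(x$loadings),
              paste(sprintf("%.2f%%", 100 * head(evr, 3)), collapse = ", ")))
  invisible(x)
}

#' @method tidy libs_pca
#' @export
tidy.libs_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$sdev), sdev = x$sdev,
                 explained_variance_ratio = x$explained_variance_ratio,
                 cumulative = cumsum(x$explained_variance_ratio))
}

#' @method glance libs_pca
#' @export
glance.libs_pca <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$loadings), n_train = x$n_train,
                 pc1_var = x$explained_variance_ratio[1],
                 pc2_var = x$explained_variance_ratio[2],
                 pc3_var = x$explained_variance_ratio[3])
}
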