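# Leave-one-out cross-validation and hyperparameter grid search.

#' Leave-one-out cross-validation accuracy
#'
#' For each sample i the classifier is fitted on all other samples and made
#' to predict sample i; the accuracy is the fraction predicted correctly. A
#' fold on which the fit or prediction fails (e.g. a single-class fold for a
#' discriminant model) is counted as an error on that fold.
#'
#' By default the scores passed in are used as-is (the PCA is fitted once on
#' the full training block before the loop). With `pca_in_fold = TRUE`,
#' `x` must be the raw spectral matrix and `n_pcs` given: each fold then
#' refits the PCA without the held-out sample — the stricter variant.
#'
#' @param x Score matrix (or raw matrix when `pca_in_fold = TRUE`).
#' @param labels Class labels.
#' @param algorithm,hyper As in [fit_classifier()].
#' @param pca_in_fold Refit the PCA inside every fold?
#' @param n_pcs Number of components (required when `pca_in_fold = TRUE`).
#' @return Accuracy fraction in \[0, 1\].
#' @export
loo_cv_accuracy <- function(x, labels, algorithm, hyper,
                            pca_in_fold = FALSE, n_pcs = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < 2L) abort("need at least 2 samples for leave-one-out")
  if (pca_in_fold) {
    if (is.null(n_pcs)) abort("n_pcs is required when pca_in_fold = TRUE")
    correct <- vapply(seq_len(n), function(i) {
      ok <- tryCatch({
        pca <- fit_pca(x[-i, , drop = FALSE], rank = n_pcs)
        fit <- fit_classifier(project(pca, x[-i, , drop = FALSE], n_pcs),
                              labels[-i], algorithm, hyper)
        pred <- predict(fit, project(pca, x[i, , drop = FALSE], n_pcs))
        as.character(pred) == labels[i]
      }, error = function(e) FALSE)
      ok
    }, logical(1))
    return(mean(correct))
  }
  if (algorithm == "knn") return(loo_knn(x, labels, as.integer(hyper)))
  correct <- vapply(seq_len(n), function(i) {
    tryCatch({
      fit <- fit_classifier(x[-i, , drop = FALSE], labels[-i], algorithm, hyper)
      as.character(predict(fit, x[i, , drop = FALSE])) == labels[i]
    }, error = function(e) FALSE)
  }, logical(1))
  mean(correct)
}

# vectorized exact-equivalent LOO for KNN: same distance/vote tie rules as
# predict_knn, with the held-out sample removed from the neighbor pool
loo_knn <- function(x, labels, k) {
  n <- nrow(x)
  if (k > n - 1L) abort(sprintf("k = %d exceeds fold size %d", k, n - 1L))
  G <- tcrossprod(x)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  correct <- vapply(seq_len(n), function(i) {
    d2 <- D2[i, -i]
    lab <- labels[-i]
    ord <- order(d2, method = "radix")
    nb <- lab[ord[seq_len(k)]]
    tab <- table(nb)
    top <- names(tab)[tab == max(tab)]
    pred <- if (length(top) == 1L) top else lab[ord[1L]]
    pred == labels[i]
  }, logical(1))
  mean(correct)
}

#' Hyperparameter grid specification
#'
#' Default grids of the workflow: 1-20 principal components for every
#' algorithm, and per algorithm KNN `k` 1-45; LDA solvers svd/lsqr/eigen;
#' QDA regularization \{0.0, 0.1, 0.2, 0.3, 0.4, 0.5\}; SVM
#' `C` \{0.1, 1, 10, 100, 1000, 10000\}.
#'
#' @param algorithm One of `"knn"`, `"lda"`, `"qda"`, `"svm"`.
#' @param pc_grid Integer vector of candidate component counts.
#' @param hyper_grid Candidate hyperparameter values (defaults above).
#' @return A `grid_spec` list.
#' @export
#' @examples
#' grid_spec("qda")
grid_spec <- function(algorithm = c("knn", "lda", "qda", "svm"),
                      pc_grid = 1:20, hyper_grid = NULL) {
  algorithm <- match.arg(algorithm)
  hyper_grid <- hyper_grid %||% switch(algorithm,
    knn = 1:45,
    lda = c("svd", "lsqr", "eigen"),
    qda = seq(0, 0.5, by = 0.1),
    svm = c(0.1, 1, 10, 100, 1000, 10000))
  if (!length(pc_grid) || !length(hyper_grid)) abort("grids must be non-empty")
  structure(list(algorithm = algorithm, pc_grid = as.integer(pc_grid),
                 hyper_grid = hyper_grid),
            class = "grid_spec")
}

#' Grid search of (number of PCs) x hyperparameter by LOO-CV
#'
#' Fits the PCA once on the full training matrix, then evaluates
#' [loo_cv_accuracy()] for every cell of the grid. The chosen cell attains
#' the maximum accuracy; ties are broken by fewer components, then by the
#' earlier hyperparameter in grid order.
#'
#' @param x Training matrix, samples x wavelengths (raw scale is fine; the
#'   function mean-centers through the PCA). Alternatively a precomputed
#'   score matrix may be supplied via `pca` = NULL only if `x` already has
#'   at most `max(pc_grid)` columns.
#' @param labels Class labels aligned with rows of `x`.
#' @param spec A [grid_spec()].
#' @param band Optional band label carried into the result.
#' @param pca_in_fold Refit the PCA inside each LOO fold (stricter, slower).
#' @return A `grid_search_map` with the accuracy matrix (rows = number of
#'   PCs, columns = hyperparameter values), the fitted `pca`, and `chosen`.
#' @export
grid_search <- function(x, labels, spec, band = NA_character_,
                        pca_in_fold = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  x <- as.matrix(x)
  max_pc <- max(spec$pc_grid)
  if (max_pc > nrow(x) - 1L) abort("pc_grid exceeds training-set size - 1")
  pca <- fit_pca(x, rank = max_pc)
  if (ncol(pca$loadings) < max_pc) abort("training matrix rank below max(pc_grid)")
  scores <- project(pca, x, max_pc)
  acc <- matrix(NA_real_, length(spec$pc_grid), length(spec$hyper_grid),
                dimnames = list(spec$pc_grid, as.character(spec$hyper_grid)))
  for (i in seq_along(spec$pc_grid)) {
    npc <- spec$pc_grid[i]
    s <- scores[, seq_len(npc), drop = FALSE]
    for (j in seq_along(spec$hyper_grid)) {
      acc[i, j] <- if (pca_in_fold) {
        loo_cv_accuracy(x, labels, spec$algorithm, spec$hyper_grid[[j]],
                        pca_in_fold = TRUE, n_pcs = npc)
      } else {
        loo_cv_accuracy(s, labels, spec$algorithm, spec$hyper_grid[[j]])
      }
    }
  }
  # argmax; ties -> fewest PCs, then earliest hyperparameter in grid order
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  structure(list(algorithm = spec$algorithm, band = band,
                 pc_grid = spec$pc_grid, hyper_grid = spec$hyper_grid,
                 accuracy = acc, pca = pca,
                 chosen = list(n_pcs = spec$pc_grid[best[1]],
                               hyper = spec$hyper_grid[[best[2]]],
                               accuracy = acc[best[1], best[2]])),
            class = "grid_search_map")
}

#' @export
print.grid_search_map <- function(x, ...) {
  cat(sprintf("<grid_search_map> %s%s: %d x %d cells, best LOO-CV accuracy %.4f at %d PCs, hyper = %s\n",
              toupper(x$algorithm),
              if (is.na(x$band)) "" else paste0(" [", x$band, "]"),
              nrow(x$accuracy), ncol(x$accuracy),
              x$chosen$accuracy, x$chosen$n_pcs, format(x$chosen$hyper)))
  invisible(x)
}

#' @method tidy grid_search_map
#' @export
tidy.grid_search_map <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, band = x$band,
    n_pcs = rep(x$pc_grid, times = length(x$hyper_grid)),
    hyper = rep(as.character(x$hyper_grid), each = length(x$pc_grid)),
    accuracy = as.vector(x$accuracy))
}

#' @method glance grid_search_map
#' @export
glance.grid_search_map <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, band = x$band,
                 n_cells = length(x$accuracy),
                 best_accuracy = x$chosen$accuracy,
                 n_pcs = x$chosen$n_pcs,
                 hyper = as.character(x$chosen$hyper))
}
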