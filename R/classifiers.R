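# The four supervised classifiers of the workflow. KNN, LDA and
# regularized QDA are implemented here because the workflow fixes exact
# tie-break and regularization semantics; the SVM is e1071's C-SVM with an
# RBF kernel and variance-scaled bandwidth.

#' Fit a vigor classifier on PCA scores
#'
#' @param x Numeric score matrix (samples x features).
#' @param labels Class labels (two classes, e.g. `"HV"` / `"LV"`).
#' @param algorithm One of `"knn"`, `"lda"`, `"qda"`, `"svm"`.
#' @param hyper The algorithm's hyperparameter: number of neighbors `k`
#'   (KNN), solver `"svd"`/`"lsqr"`/`"eigen"` (LDA; three numerical routes
#'   to the same pooled-covariance discriminant), covariance regularization
#'   `r` in \[0, 1\] (QDA: `S_r = (1 - r) S + r (tr(S)/p) I`), or soft-margin
#'   penalty `C` (SVM, RBF kernel with bandwidth `1 / (p * mean feature
#'   variance)`).
#' @param sample_ids Optional ids of the training samples, used by
#'   [external_validate()] to guard against train/validation leakage.
#' @return A `vigor_classifier` object with a [predict()][stats::predict]
#'   method returning a factor of labels.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 4), 10))
#' y <- rep(c("HV", "LV"), each = 10)
#' fit <- fit_classifier(x, y, "lda", "svd")
#' predict(fit, x)
fit_classifier <- function(x, labels, algorithm = c("knn", "lda", "qda", "svm"),
                           hyper, sample_ids = NULL) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  fit <- switch(algorithm,
    knn = fit_knn(x, labels, hyper),
    lda = fit_lda(x, labels, hyper, classes),
    qda = fit_qda(x, labels, hyper, classes),
    svm = fit_svm(x, labels, hyper))
  structure(c(fit, list(algorithm = algorithm, hyper = hyper,
                        classes = classes, sample_ids = sample_ids,
                        p = ncol(x))),
            class = "vigor_classifier")
}

fit_knn <- function(x, labels, k) {
  k <- as.integer(k)
  if (k < 1L || k > nrow(x)) abort(sprintf("k = %d outside 1..%d", k, nrow(x)))
  list(x = x, labels = labels, k = k)
}

fit_lda <- function(x, labels, solver, classes) {
  solver <- match.arg(solver, c("svd", "lsqr", "eigen"))
  if (length(classes) < 2L) abort("LDA needs at least 2 classes")
  n <- nrow(x); p <- ncol(x)
  mu <- t(sapply(classes, function(cl) colMeans(x[labels == cl, , drop = FALSE])))
  if (p == 1L) mu <- matrix(mu, ncol = 1, dimnames = list(classes, NULL))
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2, mu[cl, ], "-")
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw / (n - length(classes))
  # three numerical routes to Sw^{-1} mu_c; identical up to round-off
  w <- switch(solver,
    lsqr = t(solve(Sw, t(mu))),
    svd = {
      sv <- svd(Sw)
      pos <- sv$d > max(sv$d) * 1e-12
      inv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      mu %*% t(inv)
    },
    eigen = {
      ev <- eigen(Sw, symmetric = TRUE)
      pos <- ev$values > max(ev$values) * 1e-12
      inv <- ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
      mu %*% inv
    })
  prior <- table(factor(labels, classes)) / n
  b <- -0.5 * rowSums(w * mu) + log(as.numeric(prior))
  list(w = w, b = b)
}

fit_qda <- function(x, labels, r, classes) {
  assert_scalar_number(r, "r", min = 0, max = 1)
  if (length(classes) < 2L) abort("QDA needs at least 2 classes")
  p <- ncol(x)
  prior <- table(factor(labels, classes)) / nrow(x)
  per_class <- lapply(classes, function(cl) {
    xc <- x[labels == cl, , drop = FALSE]
    if (nrow(xc) < 2L) abort("QDA needs at least 2 samples per class")
    mu <- colMeans(xc)
    S <- cov(xc)
    Sr <- (1 - r) * S + r * (sum(diag(S)) / p) * diag(p)
    ch <- tryCatch(chol(Sr), error = function(e) {
      abort(sprintf(
        "singular class covariance for class %s with r = %g; increase the regularization",
        cl, r))
    })
    list(mu = mu, chol = ch,
         logdet = 2 * sum(log(diag(ch))), logprior = log(prior[[cl]]))
  })
  names(per_class) <- classes
  list(qda = per_class)
}

fit_svm <- function(x, labels, C) {
  assert_scalar_number(C, "C", min = 1e-12)
  mean_var <- mean(apply(x, 2, var))
  gamma <- 1 / (ncol(x) * max(mean_var, .Machine$double.eps))
  model <- e1071::svm(x, factor(labels), type = "C-classification",
                      kernel = "radial", gamma = gamma, cost = C,
                      scale = FALSE)
  list(svm = model, gamma = gamma)
}

#' @export
#' @rdname fit_classifier
#' @param object A fitted `vigor_classifier`.
#' @param newdata Score matrix to classify.
#' @param ... Unused.
predict.vigor_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) abort("feature dimension mismatch")
  out <- switch(object$algorithm,
    knn = predict_knn(object, newdata),
    lda = {
      d <- newdata %*% t(object$w)
      d <- sweep(d, 2, object$b, "+")
      object$classes[max.col(d, ties.method = "first")]
    },
    qda = {
      d <- sapply(object$qda, function(cl) {
        z <- backsolve(cl$chol, t(sweep(newdata, 2, cl$mu, "-")),
                       transpose = TRUE)
        -0.5 * cl$logdet - 0.5 * colSums(z^2) + cl$logprior
      })
      if (is.null(dim(d))) d <- matrix(d, nrow = 1)
      object$classes[max.col(d, ties.method = "first")]
    },
    svm = as.character(predict(object$svm, newdata)))
  factor(out, levels = object$classes)
}

predict_knn <- function(object, newdata) {
  k <- object$k
  train <- object$x
  vapply(seq_len(nrow(newdata)), function(i) {
    d2 <- colSums((t(train) - newdata[i, ])^2)
    # stable radix order: distance ties broken by lower training index
    ord <- order(d2, method = "radix")
    nb <- object$labels[ord[seq_len(k)]]
    tab <- table(nb)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else object$labels[ord[1L]]
  }, character(1))
}

#' @export
print.vigor_classifier <- function(x, ...) {
  cat(sprintf("<vigor_classifier> %s (hyper = %s), %d features, classes: %s\n",
              toupper(x$algorithm), format(x$hyper), x$p,
              paste(x$classes, collapse = "/")))
  invisible(x)
}
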