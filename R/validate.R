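# Train/validation splitting, final model training and external validation.

#' Stratified external-validation split
#'
#' Randomly selects `n_per_class` samples of each vigor class for external
#' validation (stratified by vigor only; cultivar is ignored), the rest
#' forming the training set. Deterministic given the seed.
#'
#' @param samples Tibble with at least `sample_id` and `vigor` columns.
#' @param n_per_class Named vector of validation counts per class
#'   (default 15 HV + 15 LV).
#' @param seed Integer RNG seed.
#' @return The input tibble with an added `set` column
#'   (`"training"`/`"validation"`).
#' @export
#' @examples
#' s <- tibble::tibble(sample_id = sprintf("S%02d", 1:40),
#'                     vigor = rep(c("HV", "LV"), each = 20))
#' dplyr::count(split_samples(s, seed = 1), vigor, set)
split_samples <- function(samples, n_per_class = c(HV = 15, LV = 15), seed) {
  stopifnot(all(c("sample_id", "vigor") %in% names(samples)))
  counts <- table(samples$vigor)
  for (cl in names(n_per_class)) {
    if (is.na(counts[cl]) || counts[cl] < n_per_class[[cl]]) {
      abort(sprintf("class %s has fewer than %d samples", cl, n_per_class[[cl]]))
    }
  }
  withr::with_seed(seed, {
    val <- unlist(lapply(names(n_per_class), function(cl) {
      ids <- samples$sample_id[samples$vigor == cl]
      sample(ids, n_per_class[[cl]])
    }))
    dplyr::mutate(samples, set = ifelse(.data$sample_id %in% val,
                                        "validation", "training"))
  })
}

#' Train the chosen model on the full training block
#'
#' Refits the classifier selected by [grid_search()] (or an explicitly given
#' `(n_pcs, hyper)` pair) on all training samples, bundling the
#' training-fitted PCA so new samples can be projected consistently.
#'
#' @param x Training matrix, samples x wavelengths.
#' @param labels Training class labels.
#' @param map A `grid_search_map`, or `NULL` if `algorithm`, `n_pcs` and
#'   `hyper` are given explicitly.
#' @param algorithm,n_pcs,hyper Explicit model choice (ignored when `map`
#'   is supplied).
#' @param sample_ids Training sample ids (for the leakage guard).
#' @param band Optional band label.
#' @return A `vigor_model` list: `pca`, `n_pcs`, `classifier`, `algorithm`,
#'   `hyper`, `band`, `sample_ids`.
#' @export
train_best <- function(x, labels, map = NULL, algorithm = NULL, n_pcs = NULL,
                       hyper = NULL, sample_ids = NULL, band = NA_character_) {
  if (!is.null(map)) {
    algorithm <- map$algorithm
    n_pcs <- map$chosen$n_pcs
    hyper <- map$chosen$hyper
    if (is.na(band)) band <- map$band
  }
  x <- as.matrix(x)
  pca <- if (!is.null(map)) map$pca else fit_pca(x, rank = n_pcs)
  scores <- project(pca, x, n_pcs)
  classifier <- fit_classifier(scores, labels, algorithm, hyper,
                               sample_ids = sample_ids)
  structure(list(pca = pca, n_pcs = n_pcs, classifier = classifier,
                 algorithm = algorithm, hyper = hyper, band = band,
                 sample_ids = sample_ids),
            class = "vigor_model")
}

#' @export
print.vigor_model <- function(x, ...) {
  cat(sprintf("<vigor_model> %s%s: %d PCs, hyper = %s\n", toupper(x$algorithm),
              if (is.na(x$band)) "" else paste0(" [", x$band, "]"),
              x$n_pcs, format(x$hyper)))
  invisible(x)
}

#' @export
#' @rdname train_best
#' @param object A `vigor_model`.
#' @param newdata Matrix of samples (rows) on the training wavelength grid.
#' @param ... Unused.
predict.vigor_model <- function(object, newdata, ...) {
  predict(object$classifier, project(object$pca, as.matrix(newdata), object$n_pcs))
}

#' Externally validate a trained model on held-out samples
#'
#' Projects the validation samples with the training-fitted PCA, predicts
#' with the trained classifier, and reports the confusion matrix and the
#' overall accuracy. Errors if any validation sample id overlaps the
#' training ids (leakage guard).
#'
#' @param model A `vigor_model` from [train_best()].
#' @param x Validation matrix (samples x wavelengths).
#' @param labels True validation labels.
#' @param sample_ids Validation sample ids (checked against training ids).
#' @return A `validation_report`: `confusion` (2x2 table, truth in rows),
#'   `accuracy`, `n`, plus algorithm/band metadata.
#' @export
external_validate <- function(model, x, labels, sample_ids = NULL) {
  if (!is.null(sample_ids) && !is.null(model$sample_ids) &&
      length(intersect(sample_ids, model$sample_ids))) {
    abort("leakage: validation samples overlap the training set")
  }
  labels <- factor(as.character(labels), levels = model$classifier$classes)
  pred <- predict(model, x)
  confusion <- table(truth = labels, predicted = pred)
  structure(list(confusion = confusion,
                 accuracy = mean(pred == labels),
                 n = length(labels),
                 algorithm = model$algorithm, band = model$band,
                 n_pcs = model$n_pcs, hyper = model$hyper),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s%s: accuracy %.3f on %d samples\n",
              toupper(x$algorithm),
              if (is.na(x$band)) "" else paste0(" [", x$band, "]"),
              x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  df <- as.data.frame(x$confusion)
  tibble::tibble(algorithm = x$algorithm, band = x$band,
                 truth = as.character(df$truth),
                 predicted = as.character(df$predicted),
                 n = df$Freq)
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, band = x$band, n = x$n,
                 n_pcs = x$n_pcs, hyper = as.character(x$hyper),
                 accuracy = x$accuracy)
}
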