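# Replicate-spectrum preprocessing: SNV normalization, SAM outlier
# rejection against the sample mean, and per-sample averaging.

#' Standard normal variate transform
#'
#' Centers and scales a single spectrum to zero mean and unit standard
#' deviation (sample sd, n - 1 denominator). SNV removes multiplicative
#' scatter/intensity differences between replicate shots.
#'
#' @param x Numeric intensity vector with at least 2 points.
#' @return The transformed vector.
#' @export
#' @examples
#' snv(c(2, 4, 6))
snv <- function(x) {
  if (length(x) < 2L) abort("degenerate spectrum: fewer than 2 points")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("degenerate spectrum: zero standard deviation")
  (x - mean(x)) / s
}

# column-wise SNV for a wavelengths x replicates matrix
snv_cols <- function(X) {
  m <- colMeans(X)
  n <- nrow(X)
  s <- sqrt((colSums(X^2) - n * m^2) / (n - 1))
  if (any(!is.finite(s) | s == 0)) abort("degenerate spectrum: zero standard deviation")
  sweep(sweep(X, 2, m, "-"), 2, s, "/")
}

#' Spectral angle mapper similarity
#'
#' Cosine of the spectral angle between two intensity vectors,
#' `<a,b> / (||a|| ||b||)`, in \[-1, 1\]. Symmetric and invariant to positive
#' rescaling of either argument; 1 means identical direction (zero angle).
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return The cosine similarity.
#' @export
#' @examples
#' sam_similarity(c(1, 1), c(1, 0)) # cos 45 degrees
sam_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("zero vector has no spectral angle")
  sum(a * b) / (na * nb)
}

#' Filter outlier replicates by SAM similarity to the replicate mean
#'
#' The reference is the pointwise arithmetic mean of all input replicates
#' (single pass: it is not recomputed after discards). A replicate survives
#' iff its SAM similarity to the reference is at least `threshold`.
#'
#' @param X Matrix of SNV-transformed replicates, one column per replicate.
#' @param threshold Similarity cut, default 0.90.
#' @param sample_id,band Optional labels carried into the report.
#' @return A list with `kept` (surviving column indices), `X` (surviving
#'   columns) and `report`, a one-row tibble with `sample_id`, `band`,
#'   `n_input`, `n_discarded`, `discarded_indices` and `sam_values`
#'   (list-columns) and `threshold`.
#' @export
filter_outliers <- function(X, threshold = 0.90, sample_id = NA_character_,
                            band = NA_character_) {
  if (ncol(X) < 2L) abort("need at least 2 replicates to filter")
  ref <- rowMeans(X)
  nref <- sqrt(sum(ref^2))
  if (nref == 0) abort("zero reference spectrum")
  sims <- as.vector(crossprod(ref, X)) / (nref * sqrt(colSums(X^2)))
  keep <- sims >= threshold
  if (!any(keep)) abort(sprintf("sample unusable: all %d replicates below SAM threshold %.2f",
                                ncol(X), threshold))
  report <- tibble::tibble(
    sample_id = sample_id, band = band,
    n_input = ncol(X), n_discarded = sum(!keep),
    discarded_indices = list(which(!keep)),
    sam_values = list(sims), threshold = threshold)
  list(kept = which(keep), X = X[, keep, drop = FALSE], report = report)
}

#' Average surviving replicates into one spectrum
#'
#' @param X Matrix with one column per surviving replicate (at least one).
#' @return The pointwise arithmetic mean vector.
#' @export
average_sample <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (ncol(X) < 1L) abort("cannot average an empty replicate set")
  rowMeans(X)
}

#' Preprocess a LIBS dataset: SNV, SAM filter, per-sample averaging
#'
#' For every sample and band: each replicate spectrum is SNV-transformed,
#' replicates whose SAM similarity to the sample's mean SNV spectrum falls
#' below `threshold` are discarded, and the survivors are averaged into one
#' spectrum per sample per band.
#'
#' @param dataset A `libs_dataset`.
#' @param threshold SAM similarity cut, default 0.90.
#' @return A list with `averaged`, an `averaged_spectra` object (per band: a
#'   samples x wavelengths matrix of averaged SNV spectra plus metadata), and
#'   `filter_report`, a tibble with one row per sample per band.
#' @export
#' @examples
#' cfg <- generator_config(
#'   composition = data.frame(cultivar = "Marandu", vigor = c("HV", "LV"),
#'                            n = c(3, 3)),
#'   replicates_per_sample = 5,
#'   bands = list(UV = list(min = 245, max = 330, step = 0.2)), seed = 7
#' )
#' pp <- preprocess_dataset(generate_dataset(cfg))
#' pp$filter_report
preprocess_dataset <- function(dataset, threshold = 0.90) {
  assert_scalar_number(threshold, "threshold", min = -1, max = 1)
  samples <- dataset$samples
  bands_out <- list()
  reports <- list()
  for (band in names(dataset$bands)) {
    b <- dataset$bands[[band]]
    A <- matrix(NA_real_, nrow(samples), length(b$wavelength),
                dimnames = list(samples$sample_id, NULL))
    for (s in seq_len(nrow(samples))) {
      cols <- b$replicates$col[b$replicates$sample_id == samples$sample_id[s]]
      Xs <- snv_cols(b$intensity[, cols, drop = FALSE])
      fl <- filter_outliers(Xs, threshold = threshold,
                            sample_id = samples$sample_id[s], band = band)
      # map surviving/discarded positions back to replicate indices
      repl <- b$replicates$replicate[cols]
      fl$report$discarded_indices <- list(repl[unlist(fl$report$discarded_indices)])
      reports[[length(reports) + 1L]] <- fl$report
      A[s, ] <- average_sample(fl$X)
    }
    bands_out[[band]] <- list(band = band, wavelength = b$wavelength, X = A)
  }
  averaged <- structure(list(samples = samples, bands = bands_out),
                        class = "averaged_spectra")
  list(averaged = averaged, filter_report = dplyr::bind_rows(reports))
}

#' @export
print.averaged_spectra <- function(x, ...) {
  cat("<averaged_spectra>\n")
  cat(sprintf("  %d samples, bands: %s\n", nrow(x$samples),
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' Extract the averaged sample matrix for one band
#'
#' @param averaged An `averaged_spectra` object from [preprocess_dataset()].
#' @param band Band name, e.g. `"UV"`.
#' @return A samples x wavelengths matrix with sample ids as row names.
#' @export
averaged_matrix <- function(averaged, band) {
  if (!band %in% names(averaged$bands)) {
    abort(sprintf("band %s not present (have: %s)", band,
                  paste(names(averaged$bands), collapse = ", ")))
  }
  averaged$bands[[band]]$X
}

#' Tidy an averaged-spectra object into a long tibble
#'
#' @param x An `averaged_spectra` object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `cultivar`, `vigor`, `band`,
#'   `wavelength`, `intensity` (one row per grid point; long format).
#' @method tidy averaged_spectra
#' @export
tidy.averaged_spectra <- function(x, ...) {
  purrr::map_dfr(x$bands, function(b) {
    tibble::tibble(
      sample_id = rep(x$samples$sample_id, each = length(b$wavelength)),
      cultivar = rep(x$samples$cultivar, each = length(b$wavelength)),
      vigor = rep(x$samples$vigor, each = length(b$wavelength)),
      band = b$band,
      wavelength = rep(b$wavelength, times = nrow(x$samples)),
      intensity = as.vector(t(b$X)))
  })
}
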