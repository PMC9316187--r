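# Shared fixtures: all synthetic, built in code at test time.

# a small, fast generator configuration (single coarse UV band)
small_config <- function(n = c(3, 3, 3, 3), reps = 6, seed = 42, ...) {
  generator_config(
    composition = data.frame(
      cultivar = c("Marandu", "Paiaguas", "Marandu", "Paiaguas"),
      vigor    = c("HV", "HV", "LV", "LV"),
      n        = n),
    replicates_per_sample = reps,
    bands = list(UV = list(min = 175, max = 330, step = 0.1)),
    seed = seed,
    ...
  )
}

# two well-separated Gaussian clusters in `p` dimensions
toy_clusters <- function(n_per_class = 6, p = 3, sep = 8, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p), n_per_class, p),
               matrix(rnorm(n_per_class * p, mean = sep), n_per_class, p))
    list(x = x, labels = rep(c("HV", "LV"), each = n_per_class))
  })
}

# independently coded explicit hold-one-out loop (oracle for loo_cv_accuracy)
explicit_loo <- function(x, labels, algorithm, hyper) {
  n <- nrow(x)
  hits <- logical(n)
  for (i in seq_len(n)) {
    hits[i] <- tryCatch({
      fit <- fit_classifier(x[-i, , drop = FALSE], labels[-i], algorithm, hyper)
      as.character(predict(fit, x[i, , drop = FALSE])) == labels[i]
    }, error = function(e) FALSE)
  }
  mean(hits)
}

# column-wise SNV via the scalar exported function (independent of the
# package's internal vectorized path)
snv_cols_for_test <- function(X) apply(X, 2, snv)

# overall desirability column of the published-style factorial table used in
# the examples (11 experiments, center point replicated three times)
od_table <- c(0.64, 0.63, 0.95, 0.68, 0.64, 0.49, 0.33, 0.30, 0.42, 0.83, 0.67)
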