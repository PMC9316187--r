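test_that("SNV centers and scales with the sample (n-1) standard deviation", {
  expect_equal(snv(c(2, 4, 6)), c(-1, 0, 1))
  expect_error(snv(c(5, 5, 5)), "degenerate")
  expect_error(snv(3), "degenerate")
  withr::with_seed(1, {
    for (i in 1:5) {
      x <- snv(rnorm(200, mean = runif(1, -5, 5), sd = runif(1, 0.1, 10)))
      expect_lt(abs(mean(x)), 1e-9)
      expect_lt(abs(sd(x) - 1), 1e-9)
    }
  })
})

test_that("SAM similarity is the cosine of the spectral angle", {
  expect_equal(sam_similarity(c(3, 1, 4), c(3, 1, 4)), 1.0)
  expect_equal(sam_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(sam_similarity(c(1, 1), c(1, 0)), 0.70711, tolerance = 1e-5)
  expect_error(sam_similarity(c(0, 0), c(1, 2)), "zero vector")
  expect_error(sam_similarity(1:3, 1:4), "equal length")
})

test_that("SAM is symmetric and invariant to positive rescaling", {
  withr::with_seed(2, {
    for (i in 1:10) {
      a <- rnorm(50); b <- rnorm(50); c <- runif(1, 0.01, 100)
      expect_equal(sam_similarity(a, b), sam_similarity(b, a))
      expect_equal(sam_similarity(c * a, b), sam_similarity(a, b), tolerance = 1e-12)
    }
  })
})

test_that("the outlier filter keeps identical replicates and flags corrupted ones", {
  X <- matrix(rep(snv(sin(1:40)), 5), ncol = 5)
  fl <- filter_outliers(X)
  expect_equal(fl$report$n_discarded, 0L)
  expect_equal(fl$report$sam_values[[1]], rep(1, 5))

  # clean replicates plus one corrupted by the generator's ground truth
  cfg <- small_config(n = c(1, 1, 1, 1), reps = 12, outlier_fraction = 0.02,
                      seed = 13)
  ds <- generate_dataset(cfg)   # 48 reps -> 1 corrupted
  expect_equal(nrow(ds$outliers), 1)
  b <- ds$bands$UV
  sid <- ds$outliers$sample_id[1]
  cols <- b$replicates$col[b$replicates$sample_id == sid]
  fl <- filter_outliers(snv_cols_for_test(b$intensity[, cols]), threshold = 0.90)
  discarded_reps <- b$replicates$replicate[cols][setdiff(seq_along(cols), fl$kept)]
  expect_equal(discarded_reps, ds$outliers$replicate[1])
})

test_that("raising the threshold never decreases the number discarded", {
  withr::with_seed(3, {
    # shared line shape plus per-replicate noise of increasing strength, so
    # the SAM values spread over a wide range
    shape <- 10 * exp(-((seq(0, 10, length.out = 200) - 5)^2))
    X <- sapply(seq(0.05, 3, length.out = 10), function(s) shape + rnorm(200, sd = s))
    X <- apply(X, 2, snv)
    n_disc <- vapply(c(0.2, 0.5, 0.8, 0.9, 0.95, 0.985), function(th) {
      filter_outliers(X, threshold = th)$report$n_discarded
    }, integer(1))
    expect_true(all(diff(n_disc) >= 0))
    expect_gt(n_disc[6], n_disc[1])
  })
})

test_that("a sample whose replicates all fail the filter is rejected as unusable", {
  X <- apply(matrix(rnorm(100 * 6), 100, 6), 2, snv)  # mutually dissimilar noise
  expect_error(filter_outliers(X, threshold = 0.999), "sample unusable")
})

test_that("averaging is the pointwise mean and is idempotent", {
  expect_equal(average_sample(matrix(c(0, 0, 2, 2), 2)), c(1, 1))
  one <- matrix(c(3, 1, 4), 3)
  expect_equal(average_sample(one), c(3, 1, 4))
  k_same <- matrix(rep(c(3, 1, 4), 4), 3)
  expect_equal(average_sample(k_same), c(3, 1, 4))
  expect_error(average_sample(matrix(numeric(), 3, 0)), "empty")
})

test_that("preprocessing averages only the surviving SNV replicates", {
  cfg <- small_config(n = c(1, 1, 1, 1), reps = 12, outlier_fraction = 0.02,
                      seed = 13)
  ds <- generate_dataset(cfg)
  pp <- preprocess_dataset(ds)
  sid <- ds$outliers$sample_id[1]
  b <- ds$bands$UV
  cols <- b$replicates$col[b$replicates$sample_id == sid]
  Xs <- apply(b$intensity[, cols], 2, snv)
  keep <- !(b$replicates$replicate[cols] %in% ds$outliers$replicate)
  manual <- rowMeans(Xs[, keep, drop = FALSE])
  row <- which(pp$averaged$samples$sample_id == sid)
  expect_equal(unname(pp$averaged$bands$UV$X[row, ]), manual, tolerance = 1e-12)
  rep_row <- pp$filter_report[pp$filter_report$sample_id == sid &
                              pp$filter_report$band == "UV", ]
  expect_equal(rep_row$n_discarded, sum(!keep))
})
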