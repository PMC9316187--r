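test_that("LOO-CV is perfect for 1-NN on far-separated clusters", {
  toy <- toy_clusters(n_per_class = 6, p = 3, sep = 10, seed = 16)
  expect_equal(loo_cv_accuracy(toy$x, toy$labels, "knn", 1), 1.0)
})

test_that("LOO-CV equals an independently coded hold-one-out loop", {
  toy <- toy_clusters(n_per_class = 6, p = 3, sep = 2, seed = 17)
  for (alg in c("knn", "lda", "qda", "svm")) {
    hyper <- switch(alg, knn = 3, lda = "lsqr", qda = 0.1, svm = 1)
    expect_equal(loo_cv_accuracy(toy$x, toy$labels, alg, hyper),
                 explicit_loo(toy$x, toy$labels, alg, hyper),
                 info = alg)
  }
  # and for KNN across several k (the internal fast path must agree exactly)
  for (k in c(1, 2, 5, 11)) {
    expect_equal(loo_cv_accuracy(toy$x, toy$labels, "knn", k),
                 explicit_loo(toy$x, toy$labels, "knn", k), info = paste0("k=", k))
  }
})

test_that("random labels on isotropic noise give chance-level LOO accuracy", {
  n <- 60  # large enough that the leave-one-out class-imbalance bias is small
  hits <- c(knn = 0, lda = 0)
  n_total <- 0
  for (seed in 1:20) {
    withr::with_seed(seed + 100, {
      x <- matrix(rnorm(n * 4), n, 4)
      y <- sample(rep(c("HV", "LV"), each = n / 2))
    })
    n_total <- n_total + n
    hits["knn"] <- hits["knn"] + n * loo_cv_accuracy(x, y, "knn", 7)
    hits["lda"] <- hits["lda"] + n * loo_cv_accuracy(x, y, "lda", "svd")
  }
  band <- 2.576 * sqrt(0.25 / n_total)
  for (alg in names(hits)) {
    expect_lt(abs(hits[[alg]] / n_total - 0.5), band + 0.05)
  }
})

test_that("grid search produces the specified map shape and a maximal chosen cell", {
  toy <- toy_clusters(n_per_class = 12, p = 8, sep = 1.2, seed = 18)
  spec <- grid_spec("knn", pc_grid = 1:4, hyper_grid = c(1, 3, 5))
  map <- grid_search(toy$x, toy$labels, spec, band = "UV")
  expect_equal(dim(map$accuracy), c(4, 3))
  expect_equal(max(map$accuracy),
               map$accuracy[as.character(map$chosen$n_pcs),
                            as.character(map$chosen$hyper)])
  td <- tidy(map)
  expect_equal(nrow(td), 12)
  expect_equal(max(td$accuracy), map$chosen$accuracy)
})

test_that("grid-search ties break toward fewer PCs then the earlier hyperparameter", {
  toy <- toy_clusters(n_per_class = 8, p = 6, sep = 30, seed = 19)
  # trivially separable: every cell is 1.0, so the tie rule decides
  spec <- grid_spec("knn", pc_grid = 2:5, hyper_grid = c(7, 1, 3))
  map <- grid_search(toy$x, toy$labels, spec)
  expect_equal(max(map$accuracy), 1)
  expect_equal(map$chosen$n_pcs, 2L)
  expect_equal(map$chosen$hyper, 7)
})

test_that("all three LDA solver columns agree on real grid searches", {
  toy <- toy_clusters(n_per_class = 10, p = 6, sep = 1.5, seed = 20)
  map <- grid_search(toy$x, toy$labels, grid_spec("lda", pc_grid = 1:5))
  expect_equal(dim(map$accuracy), c(5, 3))
  expect_lt(max(abs(map$accuracy[, 1] - map$accuracy[, 2])), 1e-12)
  expect_lt(max(abs(map$accuracy[, 1] - map$accuracy[, 3])), 1e-12)
})

test_that("the in-fold PCA variant runs and stays near the pooled-PCA answer", {
  toy <- toy_clusters(n_per_class = 8, p = 5, sep = 6, seed = 21)
  a1 <- loo_cv_accuracy(toy$x, toy$labels, "lda", "svd",
                        pca_in_fold = TRUE, n_pcs = 2)
  p <- fit_pca(toy$x, rank = 2)
  a2 <- loo_cv_accuracy(project(p, toy$x, 2), toy$labels, "lda", "svd")
  expect_equal(a1, 1.0)
  expect_equal(a2, 1.0)
})

test_that("stratified splitting is deterministic, disjoint and vigor-balanced", {
  s <- tibble::tibble(sample_id = sprintf("S%03d", 1:40),
                      vigor = rep(c("HV", "LV"), each = 20))
  sp1 <- split_samples(s, n_per_class = c(HV = 5, LV = 5), seed = 22)
  sp2 <- split_samples(s, n_per_class = c(HV = 5, LV = 5), seed = 22)
  expect_identical(sp1, sp2)
  counts <- dplyr::count(sp1, vigor, set)
  expect_equal(counts$n[counts$set == "validation"], c(5, 5))
  expect_equal(counts$n[counts$set == "training"], c(15, 15))
  expect_setequal(sp1$sample_id, s$sample_id)
  expect_error(split_samples(s[1:6, ], n_per_class = c(HV = 5, LV = 5), seed = 1),
               "fewer than")
})

test_that("external validation guards against train/validation leakage", {
  toy <- toy_clusters(n_per_class = 10, p = 4, sep = 6, seed = 23)
  ids <- sprintf("S%02d", 1:20)
  model <- train_best(toy$x, toy$labels, algorithm = "lda", n_pcs = 2,
                      hyper = "svd", sample_ids = ids[1:16])
  expect_error(external_validate(model, toy$x[15:20, ], toy$labels[15:20],
                                 sample_ids = ids[15:20]), "leakage")
  rep <- external_validate(model, toy$x[17:20, ], toy$labels[17:20],
                           sample_ids = ids[17:20])
  expect_equal(sum(rep$confusion), 4)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / 4)
  # all-wrong predictions give zero accuracy
  flipped <- ifelse(toy$labels[17:20] == "HV", "LV", "HV")
  rep2 <- external_validate(model, toy$x[17:20, ], flipped,
                            sample_ids = ids[17:20])
  expect_equal(rep2$accuracy, 0)
})

test_that("the fitted model is unchanged by anything in the validation set", {
  toy <- toy_clusters(n_per_class = 10, p = 4, sep = 3, seed = 24)
  model <- train_best(toy$x[1:16, ], toy$labels[1:16], algorithm = "qda",
                      n_pcs = 2, hyper = 0.1, sample_ids = sprintf("S%02d", 1:16))
  perm <- c(3, 1, 4, 2)
  p1 <- predict(model, toy$x[17:20, ])
  p2 <- predict(model, toy$x[17:20, ][perm, ])
  expect_identical(as.character(p1)[perm], as.character(p2))
})
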