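# End-to-end orchestration: simulate -> preprocess -> split -> grid search
# -> external validation, with reproducible per-stage seeding.

#' Full-run configuration
#'
#' Bundles the generator configuration, the split specification, the
#' hyperparameter grids, the SAM threshold and a master seed. All stage
#' seeds are derived deterministically from the master seed via
#' [stage_seed()], so adding a stage never shifts another stage's random
#' stream.
#'
#' @param generator A [generator_config()] (its `seed` is overridden by the
#'   derived simulate-stage seed unless `keep_generator_seed = TRUE`).
#' @param algorithms Algorithms to train (subset of knn/lda/qda/svm).
#' @param bands Bands to analyze (must exist in the generator config).
#' @param grids Named list of [grid_spec()]s, one per algorithm.
#' @param n_validation_per_class Held-out samples per vigor class.
#' @param sam_threshold SAM similarity cut in (0, 1].
#' @param pca_in_fold Refit PCA inside each LOO fold (stricter variant).
#' @param master_seed Integer master seed.
#' @param keep_generator_seed Keep `generator$seed` instead of deriving it.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       algorithms = c("knn", "lda", "qda", "svm"),
                       bands = names(generator$bands),
                       grids = NULL,
                       n_validation_per_class = c(HV = 15, LV = 15),
                       sam_threshold = 0.90,
                       pca_in_fold = FALSE,
                       master_seed = 1,
                       keep_generator_seed = FALSE) {
  grids <- grids %||% stats::setNames(lapply(algorithms, grid_spec), algorithms)
  cfg <- structure(list(generator = generator, algorithms = algorithms,
                        bands = bands, grids = grids,
                        n_validation_per_class = n_validation_per_class,
                        sam_threshold = sam_threshold,
                        pca_in_fold = pca_in_fold,
                        master_seed = as.integer(master_seed),
                        keep_generator_seed = keep_generator_seed),
                   class = "run_config")
  issues <- validate_config(cfg)
  if (length(issues)) abort(paste0("invalid run_config:\n- ",
                                   paste(issues, collapse = "\n- ")))
  cfg
}

#' Validate a run configuration
#'
#' @param config A `run_config`.
#' @return Character vector of issues; empty iff the configuration is
#'   runnable.
#' @export
validate_config <- function(config) {
  issues <- character()
  chk <- function(cond, msg) if (!cond) issues <<- c(issues, msg)
  chk(inherits(config$generator, "generator_config") &&
        !inherits(try(validate_generator_config(config$generator), silent = TRUE),
                  "try-error"),
      "generator configuration is invalid")
  chk(all(config$algorithms %in% c("knn", "lda", "qda", "svm")),
      paste0("unknown algorithm(s): ",
             paste(setdiff(config$algorithms, c("knn", "lda", "qda", "svm")),
                   collapse = ", ")))
  chk(all(config$bands %in% names(config$generator$bands)),
      "bands must exist in the generator configuration")
  chk(is.numeric(config$sam_threshold) && length(config$sam_threshold) == 1 &&
        config$sam_threshold > 0 && config$sam_threshold <= 1,
      "sam_threshold must lie in (0, 1]")
  chk(all(config$algorithms %in% names(config$grids)) &&
        all(vapply(config$grids, inherits, logical(1), "grid_spec")),
      "grids must provide a grid_spec for every algorithm")
  if (inherits(config$generator, "generator_config")) {
    n_class <- tapply(config$generator$composition$n,
                      config$generator$composition$vigor, sum)
    for (cl in names(config$n_validation_per_class)) {
      need <- config$n_validation_per_class[[cl]]
      chk(!is.na(n_class[cl]) && n_class[cl] >= need + 2,
          sprintf("class %s needs at least %d samples (validation + training)",
                  cl, need + 2))
    }
  }
  issues
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected; absent keys fall back to the defaults, so an
#' empty file yields the full default configuration (study composition,
#' default grids). Recognized top-level keys: `master_seed`, `algorithms`,
#' `bands`, `sam_threshold`, `pca_in_fold`, `n_validation_per_class`, and a
#' `generator` block whose keys match [generator_config()] arguments
#' (`composition` as a list of `{cultivar, vigor, n}` records).
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("master_seed", "algorithms", "bands", "sam_threshold",
                 "pca_in_fold", "n_validation_per_class", "generator")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) abort(paste0("unknown config key(s): ",
                                    paste(unknown, collapse = ", ")))
  gen_args <- list()
  if (!is.null(raw$generator)) {
    known_gen <- setdiff(names(formals(generator_config)), c("lines"))
    unknown <- setdiff(names(raw$generator), known_gen)
    if (length(unknown)) abort(paste0("unknown generator key(s): ",
                                      paste(unknown, collapse = ", ")))
    gen_args <- raw$generator
    if (!is.null(gen_args$composition)) {
      # YAML 1.1 reads a bare `n` key as the boolean FALSE; map it back
      gen_args$composition <- dplyr::bind_rows(lapply(gen_args$composition,
        function(r) { names(r)[names(r) %in% c("FALSE", "F")] <- "n"; r }))
    }
    if (!is.null(gen_args$bands)) {
      gen_args$bands <- lapply(gen_args$bands, function(b) b[c("min", "max", "step")])
    }
  }
  generator <- do.call(generator_config, gen_args)
  args <- list(generator = generator)
  if (!is.null(raw$n_validation_per_class)) {
    args$n_validation_per_class <- unlist(raw$n_validation_per_class)
  }
  for (k in c("master_seed", "algorithms", "bands", "sam_threshold", "pca_in_fold")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(run_config, args)
}

#' Classify one band of averaged spectra
#'
#' Runs, for one detector band: the training/validation sample matrices,
#' grid search by LOO-CV for each requested algorithm, refit of the chosen
#' model on the full training block, and external validation.
#'
#' @param averaged An `averaged_spectra` object.
#' @param split Split tibble from [split_samples()] (`sample_id`, `set`).
#' @param band Band name.
#' @param algorithms Algorithms to run.
#' @param grids Named list of [grid_spec()]s.
#' @param pca_in_fold Refit PCA inside LOO folds.
#' @return A tibble with one row per algorithm: chosen parameters, LOO-CV
#'   accuracy, external accuracy, and list-columns `map`
#'   (`grid_search_map`) and `report` (`validation_report`).
#' @export
classify_band <- function(averaged, split, band,
                          algorithms = c("knn", "lda", "qda", "svm"),
                          grids = NULL, pca_in_fold = FALSE) {
  grids <- grids %||% stats::setNames(lapply(algorithms, grid_spec), algorithms)
  X <- averaged_matrix(averaged, band)
  meta <- dplyr::left_join(averaged$samples, split[, c("sample_id", "set")],
                           by = "sample_id")
  tr <- meta$set == "training"
  Xtr <- X[tr, , drop = FALSE]
  Xva <- X[!tr, , drop = FALSE]
  purrr::map_dfr(algorithms, function(alg) {
    map <- grid_search(Xtr, meta$vigor[tr], grids[[alg]], band = band,
                       pca_in_fold = pca_in_fold)
    model <- train_best(Xtr, meta$vigor[tr], map = map,
                        sample_ids = meta$sample_id[tr], band = band)
    report <- external_validate(model, Xva, meta$vigor[!tr],
                                sample_ids = meta$sample_id[!tr])
    tibble::tibble(algorithm = alg, band = band,
                   n_pcs = map$chosen$n_pcs,
                   hyper = as.character(map$chosen$hyper),
                   cv_accuracy = map$chosen$accuracy,
                   accuracy = report$accuracy,
                   map = list(map), model = list(model),
                   report = list(report))
  })
}

#' Run the full pipeline in memory
#'
#' simulate -> preprocess (SNV, SAM filter, averaging) -> stratified split
#' -> per-band, per-algorithm LOO-CV grid search -> external validation.
#'
#' @param config A [run_config()].
#' @param keep_dataset Keep the raw dataset in the result (large).
#' @return A list with `results` (tibble, one row per algorithm x band),
#'   `filter_report`, `split`, `averaged`, `seeds`, `config` and optionally
#'   `dataset`.
#' @export
run_pipeline <- function(config = run_config(), keep_dataset = FALSE) {
  issues <- validate_config(config)
  if (length(issues)) abort(paste0("invalid run_config:\n- ",
                                   paste(issues, collapse = "\n- ")))
  seeds <- list(simulate = stage_seed(config$master_seed, "simulate"),
                split = stage_seed(config$master_seed, "split"))
  gen <- config$generator
  if (!config$keep_generator_seed) gen$seed <- seeds$simulate
  dataset <- generate_dataset(gen)
  pp <- preprocess_dataset(dataset, threshold = config$sam_threshold)
  n_total <- sum(pp$filter_report$n_input)
  if (!keep_dataset) rm(dataset)
  split <- split_samples(pp$averaged$samples,
                         n_per_class = config$n_validation_per_class,
                         seed = seeds$split)
  results <- purrr::map_dfr(config$bands, function(band) {
    classify_band(pp$averaged, split, band, config$algorithms, config$grids,
                  config$pca_in_fold)
  })
  out <- list(results = results, filter_report = pp$filter_report,
              discarded_fraction = sum(pp$filter_report$n_discarded) / n_total,
              split = split, averaged = pp$averaged, seeds = seeds,
              config = config)
  if (keep_dataset) out$dataset <- dataset
  out
}

#' Run the pipeline and write its artifacts to disk
#'
#' Writes one heat-map CSV per algorithm x band (rows = number of PCs,
#' columns = hyperparameter values, cells = LOO-CV accuracy to 4 decimals),
#' `filter_report.csv`, the averaged sample matrices, the split, a
#' `report.json` with chosen parameters, confusion matrices and external
#' accuracies, and a `manifest.csv` listing every written file with its
#' stage and seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run manifest tibble, invisibly; the full pipeline result is
#'   attached as attribute `"run"`.
#' @export
run_all <- function(config = run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- run_pipeline(config)
  files <- list()
  add <- function(path, stage) {
    files[[length(files) + 1L]] <<- tibble::tibble(
      stage = stage, path = path,
      seed = as.integer(run$seeds[[stage]] %||% NA_integer_))
  }
  for (band in config$bands) {
    b <- run$averaged$bands[[band]]
    avg <- tibble::as_tibble(b$X, .name_repair = "minimal")
    names(avg) <- sprintf("%.6g", b$wavelength)
    avg <- dplyr::bind_cols(tibble::tibble(sample_id = run$averaged$samples$sample_id), avg)
    f <- file.path(out_dir, paste0("averaged_", tolower(band), ".csv"))
    readr::write_csv(avg, f, progress = FALSE)
    add(f, "preprocess")
  }
  fr <- dplyr::select(run$filter_report, "sample_id", "band", "n_input",
                      "n_discarded", "threshold")
  readr::write_csv(fr, file.path(out_dir, "filter_report.csv"), progress = FALSE)
  add(file.path(out_dir, "filter_report.csv"), "preprocess")
  readr::write_csv(run$split, file.path(out_dir, "split.csv"), progress = FALSE)
  add(file.path(out_dir, "split.csv"), "split")
  for (i in seq_len(nrow(run$results))) {
    map <- run$results$map[[i]]
    hm <- tibble::as_tibble(round(map$accuracy, 4), .name_repair = "minimal")
    names(hm) <- as.character(map$hyper_grid)
    hm <- dplyr::bind_cols(tibble::tibble(n_pcs = map$pc_grid), hm)
    f <- file.path(out_dir, sprintf("heatmap_%s_%s.csv",
                                    run$results$algorithm[i],
                                    tolower(run$results$band[i])))
    readr::write_csv(hm, f, progress = FALSE)
    add(f, "train")
  }
  report <- lapply(seq_len(nrow(run$results)), function(i) {
    rep <- run$results$report[[i]]
    list(algorithm = run$results$algorithm[i], band = run$results$band[i],
         n_pcs = run$results$n_pcs[i], hyper = run$results$hyper[i],
         loo_cv_accuracy = run$results$cv_accuracy[i],
         external_accuracy = rep$accuracy,
         confusion = as.list(as.data.frame(rep$confusion)))
  })
  jsonlite::write_json(list(master_seed = config$master_seed,
                            discarded_fraction = run$discarded_fraction,
                            models = report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add(file.path(out_dir, "report.json"), "validate")
  manifest <- dplyr::bind_rows(files)
  readr::write_csv(manifest, file.path(out_dir, "run_manifest.csv"), progress = FALSE)
  attr(manifest, "run") <- run
  invisible(manifest)
}
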