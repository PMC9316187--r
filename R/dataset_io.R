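#' Write a LIBS dataset to disk
#'
#' Writes one CSV per sample per band (first column `wavelength_nm`, then one
#' column per replicate) plus a `manifest.csv` with columns `sample_id`,
#' `cultivar`, `vigor`, `band`, `path`.
#'
#' @param dataset A `libs_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (band in names(dataset$bands)) {
    b <- dataset$bands[[band]]
    for (s in seq_len(nrow(dataset$samples))) {
      sid <- dataset$samples$sample_id[s]
      cols <- b$replicates$col[b$replicates$sample_id == sid]
      df <- tibble::as_tibble(b$intensity[, cols, drop = FALSE])
      names(df) <- paste0("rep", b$replicates$replicate[cols])
      df <- dplyr::bind_cols(tibble::tibble(wavelength_nm = b$wavelength), df)
      rel <- file.path(band, paste0(sid, ".csv"))
      dir.create(file.path(dir, band), showWarnings = FALSE)
      readr::write_csv(df, file.path(dir, rel), progress = FALSE)
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        sample_id = sid, cultivar = dataset$samples$cultivar[s],
        vigor = dataset$samples$vigor[s], band = band, path = rel)
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}

#' Read a LIBS dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the per-sample CSVs.
#' @param lines Emission-line library to attach (default: shipped library).
#' @return A `libs_dataset` object (without generator config or ground-truth
#'   outlier list, which are not stored on disk).
#' @export
read_dataset <- function(dir, lines = emission_lines()) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  samples <- dplyr::distinct(manifest, .data$sample_id, .data$cultivar, .data$vigor)
  bands <- list()
  for (band in unique(manifest$band)) {
    mb <- manifest[manifest$band == band, ]
    mats <- list()
    reps <- list()
    grid <- NULL
    for (i in seq_len(nrow(mb))) {
      df <- readr::read_csv(file.path(dir, mb$path[i]), show_col_types = FALSE,
                            progress = FALSE)
      g <- df$wavelength_nm
      if (is.null(grid)) grid <- g
      else if (!isTRUE(all.equal(grid, g))) abort("replicate grids differ within a band")
      m <- as.matrix(df[, -1, drop = FALSE])
      mats[[i]] <- m
      reps[[i]] <- tibble::tibble(
        sample_id = mb$sample_id[i],
        replicate = as.integer(sub("^rep", "", colnames(m))))
    }
    X <- do.call(cbind, mats)
    replicates <- dplyr::bind_rows(reps)
    replicates$col <- seq_len(nrow(replicates))
    colnames(X) <- paste(replicates$sample_id, replicates$replicate, sep = "_r")
    bands[[band]] <- list(band = band, wavelength = grid, intensity = X,
                          replicates = replicates)
  }
  structure(list(samples = samples, bands = bands, lines = lines,
                 outliers = tibble::tibble(band = character(),
                                           sample_id = character(),
                                           replicate = integer()),
                 config = NULL),
            class = "libs_dataset")
}
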