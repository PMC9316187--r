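# Synthetic LIBS dataset generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a fixed sample composition over two cultivars and two vigor
# classes, many replicate shots per sample in two detector bands,
# vigor-linked intensity effects on Mg/Ca/K lines, cultivar-linked nuisance
# effects on Na/Si lines, per-sample and shot-to-shot log-normal amplitude
# variability, additive detector noise, and a small fraction of corrupted
# replicates.

default_base_intensities <- function(lines) {
  base <- c(
    "C I 247.856"   = 800,
    "Mn II 257.610" = 250,
    "Fe II 259.940" = 300,
    "Fe II 274.640" = 350,
    "Mg II 279.550" = 1500,
    "Mg II 280.270" = 1000,
    "Mg I 285.213"  = 600,
    "Si I 288.150"  = 700,
    "Al I 309.270"  = 400,
    "Cu I 324.750"  = 200,
    "CN I 388.350"  = 400,
    "Ca II 393.360" = 2000,
    "Al I 394.400"  = 500,
    "Ca I 422.670"  = 900,
    "Ca I 442.540"  = 350,
    "Ca I 443.590"  = 300,
    "Na I 588.995"  = 900,
    "Na I 589.590"  = 700,
    "Ca I 610.270"  = 300,
    "Ca I 612.220"  = 280,
    "Ca I 643.900"  = 250,
    "K I 766.490"   = 1200,
    "K I 769.900"   = 800
  )
  out <- base[lines$line]
  # any line not in the default table gets a modest amplitude
  out[is.na(out)] <- 300
  names(out) <- lines$line
  out
}

default_bands <- function(uv_step = 0.02, vis_step = 0.05) {
  list(
    UV  = list(min = 175, max = 330, step = uv_step),
    VIS = list(min = 275, max = 775, step = vis_step)
  )
}

#' Configuration for the synthetic LIBS dataset generator
#'
#' The defaults reproduce the study conditions of the seed-vigor analysis the
#' package implements: 120 seed samples (20 Marandu high-vigor, 40 Paiaguas
#' high-vigor, 40 Marandu low-vigor, 20 Paiaguas low-vigor), 50 replicate
#' spectra per sample in each of the UV and VIS detector bands, a
#' multiplicative vigor effect on all Mg, Ca and K emission lines, a
#' cultivar-linked nuisance effect on the Na and Si lines, log-normal
#' per-sample and shot-to-shot amplitude variability, additive Gaussian
#' noise, and 2% of replicates corrupted into outliers.
#'
#' @param composition Tibble/data frame with columns `cultivar`, `vigor`,
#'   `n`; defaults to the 120-sample study composition.
#' @param replicates_per_sample Replicate spectra per sample per band.
#' @param bands Named list of band grid specs, each `list(min, max, step)` in
#'   nm. The VIS grid extends to 775 nm so the monitored K I doublet at
#'   766.49/769.90 nm is representable.
#' @param lines Emission-line library tibble (see [emission_lines()]).
#' @param base_intensities Named vector of mean line amplitudes (a.u.), keyed
#'   by the library's `line` identifier.
#' @param vigor_effect Multiplicative factor applied to Mg/Ca/K line
#'   amplitudes for high-vigor samples (1 = no effect).
#' @param cultivar_effect Multiplicative factor applied to Na/Si line
#'   amplitudes for the Paiaguas cultivar (1 = no effect).
#' @param vigor_elements,cultivar_elements Elements carrying the vigor and
#'   cultivar effects; must be disjoint.
#' @param sample_cv Coefficient of variation of the per-sample log-normal
#'   amplitude variability (biological/matrix variation between seed lots).
#' @param shot_jitter_cv Coefficient of variation of the per-replicate,
#'   per-line multiplicative shot-to-shot fluctuation.
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.).
#' @param baseline Continuum level (a.u.).
#' @param outlier_fraction Fraction of replicate spectra per band corrupted
#'   into outliers (see [inject_outliers()]).
#' @param seed Integer RNG seed; the generator is fully deterministic given
#'   the configuration.
#' @return A validated `generator_config` object (a named list).
#' @export
#' @examples
#' cfg <- generator_config(replicates_per_sample = 5, seed = 1)
#' cfg$vigor_effect
generator_config <- function(composition = NULL,
                             replicates_per_sample = 50,
                             bands = default_bands(),
                             lines = emission_lines(),
                             base_intensities = NULL,
                             vigor_effect = 1.3,
                             cultivar_effect = 1.2,
                             vigor_elements = c("Mg", "Ca", "K"),
                             cultivar_elements = c("Na", "Si"),
                             sample_cv = 0.025,
                             shot_jitter_cv = 0.10,
                             noise_sd = 5,
                             baseline = 50,
                             outlier_fraction = 0.02,
                             seed = 20220706) {
  composition <- composition %||% tibble::tibble(
    cultivar = c("Marandu", "Paiaguas", "Marandu", "Paiaguas"),
    vigor    = c("HV", "HV", "LV", "LV"),
    n        = c(20L, 40L, 40L, 20L)
  )
  if (is.null(lines$line)) lines$line <- line_id(lines)
  base_intensities <- base_intensities %||% default_base_intensities(lines)
  cfg <- structure(list(
    composition = tibble::as_tibble(composition),
    replicates_per_sample = as.integer(replicates_per_sample),
    bands = bands,
    lines = lines,
    base_intensities = base_intensities,
    vigor_effect = vigor_effect,
    cultivar_effect = cultivar_effect,
    vigor_elements = vigor_elements,
    cultivar_elements = cultivar_elements,
    sample_cv = sample_cv,
    shot_jitter_cv = shot_jitter_cv,
    noise_sd = noise_sd,
    baseline = baseline,
    outlier_fraction = outlier_fraction,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @param config A `generator_config` object.
#' @export
validate_generator_config <- function(config) {
  comp <- config$composition
  if (nrow(comp) == 0L) abort("composition must not be empty")
  if (!all(c("cultivar", "vigor", "n") %in% names(comp))) {
    abort("composition needs columns cultivar, vigor, n")
  }
  if (any(comp$n <= 0)) abort("composition counts must be > 0")
  if (!all(comp$vigor %in% c("HV", "LV"))) abort("vigor must be \"HV\" or \"LV\"")
  assert_scalar_number(config$replicates_per_sample, "replicates_per_sample", min = 1)
  assert_scalar_number(config$outlier_fraction, "outlier_fraction", min = 0, max = 1)
  for (f in c("sample_cv", "shot_jitter_cv", "noise_sd", "baseline")) {
    assert_scalar_number(config[[f]], f, min = 0)
  }
  for (f in c("vigor_effect", "cultivar_effect")) {
    assert_scalar_number(config[[f]], f, min = 0)
  }
  if (length(intersect(config$vigor_elements, config$cultivar_elements))) {
    abort("vigor_elements and cultivar_elements must be disjoint")
  }
  if (any(config$base_intensities < 0)) abort("base_intensities must be >= 0")
  for (b in config$bands) {
    if (!(b$min < b$max) || b$step <= 0) abort("band grids need min < max and step > 0")
  }
  validate_emission_lines(config$lines)
  invisible(config)
}

band_grid <- function(band_spec) {
  seq(band_spec$min, band_spec$max, by = band_spec$step)
}

# unit-height pseudo-Voigt profile, 50/50 Gaussian/Lorentzian mix
pseudo_voigt <- function(x, center, fwhm, eta = 0.5) {
  g <- exp(-4 * log(2) * (x - center)^2 / fwhm^2)
  l <- (fwhm / 2)^2 / ((x - center)^2 + (fwhm / 2)^2)
  eta * g + (1 - eta) * l
}

# add amplitude * profile for one line into an intensity matrix block;
# the line center is snapped to the nearest grid node so the rendered peak
# height equals the amplitude exactly (step << FWHM).
line_window <- function(grid, center, halfwidth = 6) {
  step <- grid[2] - grid[1]
  i0 <- round((center - grid[1]) / step) + 1
  idx <- max(1L, i0 - round(halfwidth / step)):min(length(grid), i0 + round(halfwidth / step))
  list(idx = idx, center = grid[i0])
}

#' Render a synthetic emission spectrum
#'
#' Builds one spectrum as `baseline + sum(amplitude * profile) + noise`,
#' where each line profile is a unit-height pseudo-Voigt (50/50
#' Gaussian/Lorentzian mix) with the line's FWHM. Line centers are snapped to
#' the nearest grid node, so the rendered peak of each line lies within one
#' grid step of its nominal wavelength and its height equals the amplitude.
#'
#' @param lines Tibble of lines to render, with columns `wavelength_nm`,
#'   `fwhm_nm` and `amplitude` (plus anything else, ignored).
#' @param wavelength Strictly increasing wavelength grid (nm).
#' @param baseline Continuum level (a.u.).
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.).
#' @return A tibble with columns `wavelength` and `intensity`.
#' @export
#' @examples
#' grid <- seq(390, 396, by = 0.02)
#' sp <- render_spectrum(
#'   tibble::tibble(wavelength_nm = 393.36, fwhm_nm = 0.2, amplitude = 100),
#'   grid
#' )
#' sp$wavelength[which.max(sp$intensity)]
render_spectrum <- function(lines, wavelength, baseline = 0, noise_sd = 0) {
  stopifnot(is.numeric(wavelength), length(wavelength) >= 2)
  if (any(diff(wavelength) <= 0)) abort("wavelength grid must be strictly increasing")
  if (nrow(lines) > 0 && is.null(lines$amplitude)) abort("lines need an `amplitude` column")
  if (nrow(lines) > 0 && any(lines$amplitude < 0)) abort("amplitudes must be >= 0")
  out <- range(wavelength)
  outside <- nrow(lines) > 0 &
    (lines$wavelength_nm < out[1] | lines$wavelength_nm > out[2])
  if (any(outside)) {
    bad <- lines[outside, ]
    bad_id <- if (!is.null(bad$line)) bad$line else format(bad$wavelength_nm)
    abort(paste0("line center outside grid range: ", paste(bad_id, collapse = ", ")))
  }
  intensity <- rep(baseline, length(wavelength))
  if (nrow(lines) > 0) {
    for (i in seq_len(nrow(lines))) {
      w <- line_window(wavelength, lines$wavelength_nm[i])
      intensity[w$idx] <- intensity[w$idx] +
        lines$amplitude[i] * pseudo_voigt(wavelength[w$idx], w$center, lines$fwhm_nm[i])
    }
  }
  if (noise_sd > 0) intensity <- intensity + rnorm(length(intensity), sd = noise_sd)
  tibble::tibble(wavelength = wavelength, intensity = intensity)
}

#' Generate a synthetic LIBS seed-vigor dataset
#'
#' Draws per-sample line amplitudes (base amplitude x vigor effect x cultivar
#' effect x per-sample log-normal variability), then renders
#' `replicates_per_sample` spectra per sample per band with per-replicate
#' log-normal shot jitter on every line, a flat continuum and additive
#' Gaussian noise. If `config$outlier_fraction > 0`, a corresponding fraction
#' of replicates in each band is corrupted via [inject_outliers()] and the
#' ground-truth corruption list is stored in the result.
#'
#' The generator is fully deterministic given the configuration (including
#' its seed).
#'
#' @param config A [generator_config()] object.
#' @return A `libs_dataset` object: a list with elements `samples` (tibble of
#'   sample metadata), `bands` (per band: wavelength grid, an intensity
#'   matrix with one column per replicate, and a replicate index tibble),
#'   `lines`, `outliers` (ground-truth corrupted replicates) and `config`.
#' @export
#' @examples
#' cfg <- generator_config(
#'   composition = data.frame(cultivar = c("Marandu", "Marandu"),
#'                            vigor = c("HV", "LV"), n = c(3, 3)),
#'   replicates_per_sample = 4,
#'   bands = list(UV = list(min = 245, max = 330, step = 0.1)),
#'   seed = 1
#' )
#' ds <- generate_dataset(cfg)
#' ds
generate_dataset <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, {
    comp <- config$composition
    samples <- tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(sum(comp$n))),
      cultivar  = rep(comp$cultivar, comp$n),
      vigor     = rep(comp$vigor, comp$n)
    )
    n_samples <- nrow(samples)
    reps <- config$replicates_per_sample
    lines <- config$lines
    n_lines <- nrow(lines)
    amp0 <- config$base_intensities[lines$line]

    vig_line <- lines$element %in% config$vigor_elements
    cult_line <- lines$element %in% config$cultivar_elements
    vig_mult <- outer(vig_line, samples$vigor == "HV",
                      function(l, s) ifelse(l & s, config$vigor_effect, 1))
    cult_mult <- outer(cult_line, samples$cultivar == "Paiaguas",
                       function(l, s) ifelse(l & s, config$cultivar_effect, 1))
    # log-normal with unit mean and the requested CV
    ln_sd <- function(cv) sqrt(log(1 + cv^2))
    s_sd <- ln_sd(config$sample_cv)
    sample_amp <- amp0 * vig_mult * cult_mult *
      matrix(rlnorm(n_lines * n_samples, meanlog = -s_sd^2 / 2, sdlog = s_sd),
             n_lines, n_samples)

    j_sd <- ln_sd(config$shot_jitter_cv)
    bands <- list()
    for (band in names(config$bands)) {
      grid <- band_grid(config$bands[[band]])
      in_band <- lines$wavelength_nm >= grid[1] & lines$wavelength_nm <= grid[length(grid)]
      bl <- which(in_band)
      wins <- lapply(bl, function(i) line_window(grid, lines$wavelength_nm[i]))
      profs <- lapply(seq_along(bl), function(k) {
        pseudo_voigt(grid[wins[[k]]$idx], wins[[k]]$center, lines$fwhm_nm[bl[k]])
      })
      X <- matrix(0, length(grid), n_samples * reps)
      for (s in seq_len(n_samples)) {
        cols <- (s - 1L) * reps + seq_len(reps)
        block <- matrix(rnorm(length(grid) * reps, mean = config$baseline,
                              sd = config$noise_sd), length(grid), reps)
        if (length(bl)) {
          jitter <- matrix(rlnorm(length(bl) * reps, meanlog = -j_sd^2 / 2,
                                  sdlog = j_sd), length(bl), reps)
          amps <- sample_amp[bl, s] * jitter
          for (k in seq_along(bl)) {
            block[wins[[k]]$idx, ] <- block[wins[[k]]$idx, ] +
              tcrossprod(profs[[k]], amps[k, ])
          }
        }
        X[, cols] <- block
      }
      replicates <- tibble::tibble(
        sample_id = rep(samples$sample_id, each = reps),
        replicate = rep(seq_len(reps), n_samples),
        col = seq_len(n_samples * reps)
      )
      colnames(X) <- paste(replicates$sample_id, replicates$replicate, sep = "_r")
      bands[[band]] <- list(band = band, wavelength = grid, intensity = X,
                            replicates = replicates)
    }
    ds <- structure(list(samples = samples, bands = bands, lines = lines,
                         outliers = tibble::tibble(band = character(),
                                                   sample_id = character(),
                                                   replicate = integer()),
                         config = config),
                    class = "libs_dataset")
    if (config$outlier_fraction > 0) {
      inj <- inject_outliers(ds, config$outlier_fraction)
      ds <- inj$dataset
      ds$outliers <- inj$corrupted
    }
    ds
  })
}

#' @export
print.libs_dataset <- function(x, ...) {
  cat("<libs_dataset>\n")
  cat(sprintf("  %d samples (%d HV, %d LV), %d replicates/sample/band\n",
              nrow(x$samples), sum(x$samples$vigor == "HV"),
              sum(x$samples$vigor == "LV"), x$config$replicates_per_sample))
  for (b in x$bands) {
    cat(sprintf("  band %s: %.2f-%.2f nm, %d points, %d replicate spectra\n",
                b$band, b$wavelength[1], b$wavelength[length(b$wavelength)],
                length(b$wavelength), ncol(b$intensity)))
  }
  cat(sprintf("  corrupted replicates: %d\n", nrow(x$outliers)))
  invisible(x)
}

#' Corrupt a fraction of replicate spectra into outliers
#'
#' For each band, `round(n_replicates * fraction)` replicates (rounding half
#' away from zero) are drawn at random and distorted by a random non-empty
#' subset of three distortions: a strong baseline ramp, suppression of the
#' strongest emission lines, and a broad spurious amplitude spike. Each
#' distortion is strong enough on its own that the corrupted replicate's
#' SNV-SAM similarity to its sample mean falls well below the 0.90 filter
#' threshold.
#'
#' @param dataset A `libs_dataset` from [generate_dataset()].
#' @param fraction Fraction of replicates per band to corrupt, in \[0, 1\].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream
#'   (which is how [generate_dataset()] calls it, keeping the whole dataset
#'   deterministic under the generator seed).
#' @return A list with `dataset` (the corrupted copy) and `corrupted`, a
#'   tibble of ground truth (`band`, `sample_id`, `replicate`, `distortions`).
#' @export
inject_outliers <- function(dataset, fraction, seed = NULL) {
  assert_scalar_number(fraction, "fraction", min = 0, max = 1)
  run <- function() {
    corrupted <- list()
    for (band in names(dataset$bands)) {
      b <- dataset$bands[[band]]
      n_tot <- ncol(b$intensity)
      n_corrupt <- as.integer(round_half_up(n_tot * fraction))
      if (n_corrupt == 0L) next
      cols <- sample.int(n_tot, n_corrupt)
      grid <- b$wavelength
      # strongest 60% of this band's lines, for the suppression distortion
      in_band <- dataset$lines$wavelength_nm >= grid[1] &
        dataset$lines$wavelength_nm <= grid[length(grid)]
      bl <- dataset$lines[in_band, ]
      amps <- dataset$config$base_intensities[bl$line]
      strong <- bl[order(amps, decreasing = TRUE), ]
      strong <- strong[seq_len(ceiling(0.6 * nrow(strong))), , drop = FALSE]
      kinds <- character(n_corrupt)
      for (j in seq_along(cols)) {
        x <- b$intensity[, cols[j]]
        which_d <- sample(c("ramp", "suppress", "spike"), sample.int(3, 1))
        if ("ramp" %in% which_d) {
          x <- x + 3 * diff(range(x)) * seq(-1, 1, length.out = length(x))
        }
        if ("suppress" %in% which_d && nrow(strong)) {
          m <- median(x)
          for (i in seq_len(nrow(strong))) {
            w <- line_window(grid, strong$wavelength_nm[i], halfwidth = 1)
            x[w$idx] <- m
          }
        }
        if ("spike" %in% which_d) {
          center <- runif(1, grid[1] + 0.1 * diff(range(grid)),
                          grid[length(grid)] - 0.1 * diff(range(grid)))
          x <- x + 10 * max(abs(x)) * pseudo_voigt(grid, center, fwhm = 2)
        }
        b$intensity[, cols[j]] <- x
        kinds[j] <- paste(which_d, collapse = "+")
      }
      dataset$bands[[band]] <- b
      corrupted[[band]] <- tibble::tibble(
        band = band,
        sample_id = b$replicates$sample_id[cols],
        replicate = b$replicates$replicate[cols],
        distortions = kinds
      )
    }
    out <- dplyr::bind_rows(corrupted)
    if (nrow(out)) out <- dplyr::arrange(out, .data$band, .data$sample_id, .data$replicate)
    list(dataset = dataset,
         corrupted = if (nrow(out)) out else tibble::tibble(
           band = character(), sample_id = character(), replicate = integer(),
           distortions = character()))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
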