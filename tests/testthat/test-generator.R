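test_that("render_spectrum handles the identity, unit-height and linearity cases", {
  grid <- seq(390, 396, by = 0.02)
  flat <- render_spectrum(tibble::tibble(wavelength_nm = numeric(),
                                         fwhm_nm = numeric(),
                                         amplitude = numeric()), grid)
  expect_equal(flat$intensity, rep(0, length(grid)))

  line <- tibble::tibble(wavelength_nm = 393.36, fwhm_nm = 0.2, amplitude = 100)
  sp <- render_spectrum(line, grid, baseline = 7)
  peak_at <- sp$wavelength[which.max(sp$intensity)]
  expect_lte(abs(peak_at - 393.36), 0.02)
  expect_equal(max(sp$intensity), 107)

  sp2 <- render_spectrum(dplyr::mutate(line, amplitude = 200), grid, baseline = 7)
  expect_equal(max(sp2$intensity) - 7, 2 * (max(sp$intensity) - 7))
})

test_that("render_spectrum rejects a line outside the grid, naming it", {
  grid <- seq(390, 396, by = 0.02)
  bad <- tibble::tibble(wavelength_nm = 766.49, fwhm_nm = 0.2, amplitude = 10,
                        line = "K I 766.490")
  expect_error(render_spectrum(bad, grid), "K I 766.490")
})

test_that("the default composition is the 120-sample study structure", {
  cfg <- generator_config(replicates_per_sample = 2)
  comp <- cfg$composition
  expect_equal(sum(comp$n), 120)
  expect_equal(sum(comp$n[comp$vigor == "HV"]), 60)
  expect_equal(sum(comp$n[comp$vigor == "LV"]), 60)
  expect_equal(comp$n[comp$cultivar == "Marandu" & comp$vigor == "HV"], 20)
  expect_equal(comp$n[comp$cultivar == "Paiaguas" & comp$vigor == "LV"], 20)
})

test_that("generated datasets match the configured composition and replicate counts", {
  cfg <- small_config(n = c(2, 4, 4, 2), reps = 5)
  ds <- generate_dataset(cfg)
  expect_s3_class(ds, "libs_dataset")
  expect_equal(nrow(ds$samples), 12)
  expect_equal(sum(ds$samples$vigor == "HV"), 6)
  counts <- dplyr::count(ds$bands$UV$replicates, sample_id)
  expect_true(all(counts$n == 5))
  expect_equal(ncol(ds$bands$UV$intensity), 12 * 5)
})

test_that("generation is bit-identical under the same seed", {
  ds1 <- generate_dataset(small_config(seed = 7))
  ds2 <- generate_dataset(small_config(seed = 7))
  expect_identical(ds1$bands$UV$intensity, ds2$bands$UV$intensity)
  expect_identical(ds1$outliers, ds2$outliers)
  ds3 <- generate_dataset(small_config(seed = 8))
  expect_false(identical(ds1$bands$UV$intensity, ds3$bands$UV$intensity))
})

test_that("increasing the vigor effect strictly increases the HV-LV Mg peak gap", {
  mg_peak_gap <- function(effect) {
    cfg <- small_config(n = c(2, 2, 2, 2), reps = 1, seed = 5,
                        vigor_effect = effect, sample_cv = 0,
                        shot_jitter_cv = 0, noise_sd = 0, outlier_fraction = 0)
    ds <- generate_dataset(cfg)
    b <- ds$bands$UV
    win <- b$wavelength >= 279.25 & b$wavelength <= 279.85
    peaks <- apply(b$intensity[win, ], 2, max)
    sample_of_col <- b$replicates$sample_id
    vig <- ds$samples$vigor[match(sample_of_col, ds$samples$sample_id)]
    mean(peaks[vig == "HV"]) - mean(peaks[vig == "LV"])
  }
  gaps <- vapply(c(1, 1.3, 1.6), mg_peak_gap, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_lt(abs(gaps[1]), 1e-8)
})

test_that("with no class effects HV and LV peak heights are exchangeable", {
  rejections <- 0L
  for (seed in 1:20) {
    cfg <- small_config(n = c(3, 3, 3, 3), reps = 1, seed = seed,
                        vigor_effect = 1, cultivar_effect = 1,
                        outlier_fraction = 0)
    ds <- generate_dataset(cfg)
    b <- ds$bands$UV
    win <- b$wavelength >= 279.25 & b$wavelength <= 279.85
    peaks <- apply(b$intensity[win, ], 2, max)
    vig <- ds$samples$vigor[match(b$replicates$sample_id, ds$samples$sample_id)]
    p <- t.test(peaks[vig == "HV"], peaks[vig == "LV"])$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  # expected false-positive count at alpha = 0.01 over 20 draws is 0.2
  expect_lte(rejections, 2L)
})

test_that("outlier injection respects the per-band rounding rule and ground truth", {
  cfg <- small_config(n = c(2, 2, 1, 1), reps = 5, outlier_fraction = 0)
  ds <- generate_dataset(cfg)
  same <- inject_outliers(ds, fraction = 0, seed = 3)
  expect_identical(same$dataset$bands$UV$intensity, ds$bands$UV$intensity)
  expect_equal(nrow(same$corrupted), 0)

  # 6 samples x 5 reps = 30 replicates; 0.05 * 30 = 1.5 -> 2 (half away from zero)
  inj <- inject_outliers(ds, fraction = 0.05, seed = 3)
  expect_equal(nrow(inj$corrupted), 2)
  changed <- colSums(inj$dataset$bands$UV$intensity != ds$bands$UV$intensity) > 0
  expect_equal(sum(changed), 2)
})

test_that("every corrupted replicate falls below the SAM threshold against its clean mean", {
  cfg <- small_config(n = c(3, 3, 3, 3), reps = 10, outlier_fraction = 0.05, seed = 11)
  ds <- generate_dataset(cfg)
  expect_gt(nrow(ds$outliers), 0)
  b <- ds$bands$UV
  for (i in seq_len(nrow(ds$outliers))) {
    sid <- ds$outliers$sample_id[i]
    cols <- b$replicates$col[b$replicates$sample_id == sid]
    bad_col <- b$replicates$col[b$replicates$sample_id == sid &
                                b$replicates$replicate == ds$outliers$replicate[i]]
    bad_reps <- ds$outliers$replicate[ds$outliers$sample_id == sid &
                                      ds$outliers$band == "UV"]
    clean <- cols[!(b$replicates$replicate[match(cols, b$replicates$col)] %in% bad_reps)]
    ref <- rowMeans(apply(b$intensity[, clean, drop = FALSE], 2, snv))
    expect_lt(sam_similarity(snv(b$intensity[, bad_col]), ref), 0.90)
  }
})
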