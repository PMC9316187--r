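test_that("the factorial design has 11 runs with the fixed coded-to-real map", {
  d <- factorial_design()
  expect_equal(nrow(d), 11)
  expect_equal(sum(d$is_center), 3)
  expect_equal(nrow(dplyr::distinct(d[!d$is_center,
    c("energy_coded", "delay_coded", "gate_coded")])), 8)
  # run 3: coded (+1, -1, +1) -> (54.86 mJ, 0.50 us, 20.00 us)
  expect_equal(unlist(d[3, c("energy_coded", "delay_coded", "gate_coded")]),
               c(energy_coded = 1, delay_coded = -1, gate_coded = 1))
  expect_equal(unlist(d[3, c("energy_mj", "delay_us", "gate_us")]),
               c(energy_mj = 54.86, delay_us = 0.50, gate_us = 20.00))
  for (e in 9:11) {
    expect_equal(unlist(d[e, c("energy_mj", "delay_us", "gate_us")]),
                 c(energy_mj = 42.29, delay_us = 1.00, gate_us = 11.00))
  }
})

test_that("SBR is (peak - background)/background and scale invariant", {
  lines <- emission_lines()
  ca <- lines[lines$line == "Ca II 393.360", ]
  grid <- seq(388, 398, by = 0.02)
  # idealized flat background 10 with a single peak of height 100 at the center
  intensity <- rep(10, length(grid))
  intensity[which.min(abs(grid - ca$wavelength_nm))] <- 100
  expect_equal(sbr(grid, intensity, ca), 9.0, tolerance = 1e-12)

  flat <- rep(10, length(grid))
  expect_equal(sbr(grid, flat, ca), 0.0, tolerance = 1e-12)

  expect_equal(sbr(grid, 2 * intensity, ca), sbr(grid, intensity, ca),
               tolerance = 1e-12)
  # rendered profiles put a little wing intensity into the background windows,
  # so the rendered-line SBR sits just below the idealized ratio
  sp <- render_spectrum(dplyr::mutate(ca, amplitude = 90), grid, baseline = 10)
  expect_equal(sbr(grid, sp$intensity, ca), 9.0, tolerance = 0.05)
  expect_error(sbr(grid, intensity - 100, ca), "SBR undefined")
})

test_that("individual desirability is larger-is-better min-max scaling", {
  expect_equal(desirability(c(10, 20, 30)), c(0, 0.5, 1))
  expect_warning(di <- desirability(rep(7, 5)), "degenerate")
  expect_equal(di, rep(0.5, 5))
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- rnorm(11)
      di <- desirability(x)
      expect_equal(min(di), 0)
      expect_equal(max(di), 1)
      # invariance under positive affine rescaling of the response
      expect_equal(desirability(3.7 * x + 42), di, tolerance = 1e-12)
    }
  })
})

test_that("overall desirability is the arithmetic mean of line desirabilities", {
  expect_equal(overall_desirability(c(0.9, 1.0)), 0.95)
  expect_equal(overall_desirability(rep(0, 4)), 0)     # finite where geometric mean is not informative
  expect_equal(overall_desirability(rep(1, 4)), 1)
  expect_error(overall_desirability(numeric()), "empty")
  withr::with_seed(5, {
    di <- runif(10)
    expect_equal(overall_desirability(di), overall_desirability(sample(di)))
    bumped <- di; bumped[3] <- min(1, di[3] + 0.2)
    expect_gte(overall_desirability(bumped), overall_desirability(di))
  })
})

test_that("select_best picks the highest-OD experiment, ties to the lowest id", {
  expect_equal(select_best(od_table), 3)
  expect_equal(max(od_table), 0.95)
  expect_equal(select_best(rep(0.5, 11)), 1)
  expect_equal(select_best(0.7), 1)
})

test_that("main effects match an independent regression-contrast oracle", {
  d <- factorial_design()
  expect_equal(main_effects(d, response = rep(4, 11))$effect, rep(0, 7))

  eff <- main_effects(d, response = d$energy_coded)
  expect_equal(eff$effect[eff$term == "energy"], 2)
  expect_equal(sum(abs(eff$effect[eff$term != "energy"])), 0)

  # oracle: effects are twice the coefficients of the full coded regression
  eff <- main_effects(d, response = od_table)
  corners <- d[!d$is_center, ]
  fit <- lm(od_table[1:8] ~ energy_coded * delay_coded * gate_coded, data = corners)
  co <- 2 * coef(fit)[-1]
  expect_equal(eff$effect[eff$term == "energy"], unname(co["energy_coded"]))
  expect_equal(eff$effect[eff$term == "delay"], unname(co["delay_coded"]))
  expect_equal(eff$effect[eff$term == "gate"], unname(co["gate_coded"]))
  expect_equal(eff$effect[eff$term == "energy:delay"],
               unname(co["energy_coded:delay_coded"]))
  expect_equal(eff$effect[eff$term == "energy:delay:gate"],
               unname(co["energy_coded:delay_coded:gate_coded"]))

  expect_error(main_effects(d[-3, ], response = od_table[-3]), "corner")
})

test_that("desirability selection recovers a dominant design point from spectra", {
  lines <- emission_lines()
  grid <- seq(175, 775, by = 0.1)
  scale <- c(0.6, 0.7, 1.5, 0.8, 0.6, 0.5, 0.4, 0.3, 0.5, 0.9, 0.7)
  spectra <- simulate_doe_spectra(scale, lines, grid, replicates = 3, seed = 2)
  res <- doe_results(spectra, lines)
  expect_s3_class(res, "doe_result")
  expect_true(all(res$di$di >= 0 & res$di$di <= 1))
  expect_equal(nrow(res$od), 11)
  # OD equals the mean of the per-line desirabilities
  od3 <- mean(res$di$di[res$di$experiment == 3])
  expect_equal(res$od$od[3], od3)
  expect_equal(select_best(res), 3)
  expect_equal(glance(res)$best_experiment, 3)
})
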