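# Two-level, three-factor factorial design with center point for optimizing
# LIBS acquisition conditions, scored by per-line signal-to-background
# ratios aggregated through desirability functions.

factor_levels <- list(
  energy = c("-1" = 29.73, "0" = 42.29, "1" = 54.86),  # laser pulse energy, mJ
  delay  = c("-1" = 0.50,  "0" = 1.00,  "1" = 1.50),   # delay time, us
  gate   = c("-1" = 1.00,  "0" = 11.00, "1" = 20.00)   # signal acquisition time, us
)

#' The 2^3 factorial design with center point
#'
#' Eleven experiments: the eight corner combinations of coded levels
#' (+/-1) for laser pulse energy, delay time and signal acquisition (gate)
#' time, followed by three center-point replicates (coded 0). The coded-to-
#' real mapping is energy \{29.73, 42.29, 54.86\} mJ, delay \{0.5, 1.0, 1.5\}
#' us, gate \{1, 11, 20\} us.
#'
#' @return A tibble with columns `experiment`, coded levels
#'   (`energy_coded`, `delay_coded`, `gate_coded`), real levels (`energy_mj`,
#'   `delay_us`, `gate_us`) and `is_center`.
#' @export
#' @examples
#' factorial_design()
factorial_design <- function() {
  coded <- rbind(
    c( 1,  1,  1), c( 1,  1, -1), c( 1, -1,  1), c( 1, -1, -1),
    c(-1,  1,  1), c(-1,  1, -1), c(-1, -1,  1), c(-1, -1, -1),
    c( 0,  0,  0), c( 0,  0,  0), c( 0,  0,  0))
  tibble::tibble(
    experiment = seq_len(nrow(coded)),
    energy_coded = coded[, 1], delay_coded = coded[, 2], gate_coded = coded[, 3],
    energy_mj = unname(factor_levels$energy[as.character(coded[, 1])]),
    delay_us  = unname(factor_levels$delay[as.character(coded[, 2])]),
    gate_us   = unname(factor_levels$gate[as.character(coded[, 3])]),
    is_center = rowSums(coded != 0) == 0)
}

#' Signal-to-background ratio of one emission line
#'
#' `SBR = (I_peak - I_bg) / I_bg`, where `I_peak` is the maximum intensity
#' inside the line's signal window and `I_bg` the mean intensity over the
#' line's two flanking background windows. Negative values indicate a peak
#' below the local continuum.
#'
#' @param wavelength,intensity The spectrum (equal-length vectors).
#' @param line A one-row emission-line tibble (see [emission_lines()]).
#' @return The dimensionless SBR.
#' @export
sbr <- function(wavelength, intensity, line) {
  stopifnot(length(wavelength) == length(intensity), nrow(line) == 1L)
  sig <- wavelength >= line$wavelength_nm - line$signal_halfwidth_nm &
         wavelength <= line$wavelength_nm + line$signal_halfwidth_nm
  bg <- (wavelength >= line$bg_lo_start & wavelength <= line$bg_lo_end) |
        (wavelength >= line$bg_hi_start & wavelength <= line$bg_hi_end)
  if (!any(sig) || !any(bg)) {
    abort(sprintf("signal/background windows of line %s outside the grid",
                  line_id(line)))
  }
  i_bg <- mean(intensity[bg])
  if (i_bg <= 0) abort(sprintf("background <= 0 for line %s: SBR undefined", line_id(line)))
  (max(intensity[sig]) - i_bg) / i_bg
}

#' Individual desirability of a response across experiments
#'
#' One-sided larger-is-better linear (min-max) scaling of a response vector
#' across experiments: the experiment with the highest SBR gets desirability
#' 1, the lowest gets 0. If all responses are equal the response carries no
#' preference information; every experiment gets 0.5 and a warning is
#' issued.
#'
#' @param x Numeric response (e.g. one line's SBR) over the experiments.
#' @return Desirability vector in \[0, 1\].
#' @export
#' @examples
#' desirability(c(10, 20, 30))
desirability <- function(x) {
  if (length(x) < 2L) abort("need at least 2 experiments")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warn("degenerate response: all values equal; desirability set to 0.5")
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Overall desirability
#'
#' Aggregates per-line individual desirabilities by their arithmetic mean
#' (rather than the usual geometric mean, which collapses to zero whenever
#' any single line has desirability 0).
#'
#' @param di Vector of individual desirabilities, all in \[0, 1\].
#' @return The overall desirability in \[0, 1\].
#' @export
overall_desirability <- function(di) {
  if (length(di) == 0L) abort("empty desirability vector")
  if (any(di < 0 | di > 1)) abort("desirabilities must lie in [0, 1]")
  mean(di)
}

#' Select the best experiment by overall desirability
#'
#' @param od Numeric vector of overall desirabilities, one per experiment
#'   (in experiment order), or a `doe_result` from [doe_results()].
#' @return The 1-based experiment id attaining the maximum (ties broken by
#'   the lowest experiment id).
#' @export
#' @examples
#' select_best(c(0.64, 0.63, 0.95, 0.68, 0.64, 0.49, 0.33, 0.30, 0.42, 0.83, 0.67))
select_best <- function(od) {
  if (inherits(od, "doe_result")) od <- od$od$od
  if (length(od) == 0L) abort("no experiments")
  which.max(od)
}

#' Main effects and interaction contrasts of the factorial design
#'
#' For each factor, the effect is the mean response at its +1 corners minus
#' the mean at its -1 corners (over the eight corner runs; center points are
#' ignored). Two- and three-factor interactions use the standard products of
#' coded columns as contrasts.
#'
#' @param design A design tibble from [factorial_design()] (or its corner
#'   subset) with a `response` column, or a design plus `response` vector.
#' @param response Optional numeric response aligned with `design` rows.
#' @return A tibble with columns `term` and `effect`.
#' @export
main_effects <- function(design, response = NULL) {
  if (!is.null(response)) design$response <- response
  if (is.null(design$response)) abort("a response is required")
  corners <- design[!design$is_center, ]
  key <- paste(corners$energy_coded, corners$delay_coded, corners$gate_coded)
  full <- expand.grid(e = c(-1, 1), d = c(-1, 1), g = c(-1, 1))
  if (nrow(corners) != 8L ||
      !setequal(key, paste(full$e, full$d, full$g))) {
    abort("full corner set (all 8 +/-1 combinations) is required")
  }
  contrasts <- list(
    energy = corners$energy_coded,
    delay = corners$delay_coded,
    gate = corners$gate_coded,
    `energy:delay` = corners$energy_coded * corners$delay_coded,
    `energy:gate` = corners$energy_coded * corners$gate_coded,
    `delay:gate` = corners$delay_coded * corners$gate_coded,
    `energy:delay:gate` = corners$energy_coded * corners$delay_coded * corners$gate_coded)
  tibble::tibble(
    term = names(contrasts),
    effect = unname(purrr::map_dbl(contrasts, function(ct) {
      mean(corners$response[ct == 1]) - mean(corners$response[ct == -1])
    })))
}

#' Score factorial experiments: SBR per line, desirability, OD
#'
#' Computes, for each experiment, the mean SBR of every monitored line over
#' that experiment's replicate spectra; converts each line's SBR profile
#' across experiments into individual desirabilities; and aggregates lines
#' into the overall desirability per experiment.
#'
#' @param spectra A named/ordered list with one element per experiment, each
#'   a list with `wavelength` (grid) and `intensity` (vector, or matrix with
#'   one column per replicate spectrum).
#' @param lines Emission-line tibble of the monitored lines.
#' @param design Design tibble, default [factorial_design()].
#' @return A `doe_result`: list of tibbles `sbr` (experiment x line), `di`
#'   (experiment x line) and `od` (per experiment), plus the design.
#' @export
doe_results <- function(spectra, lines, design = factorial_design()) {
  if (length(spectra) != nrow(design)) {
    abort(sprintf("expected %d experiments, got %d", nrow(design), length(spectra)))
  }
  if (is.null(lines$line)) lines$line <- line_id(lines)
  sbr_tbl <- purrr::map_dfr(seq_along(spectra), function(e) {
    sp <- spectra[[e]]
    M <- sp$intensity
    if (is.null(dim(M))) M <- matrix(M, ncol = 1)
    purrr::map_dfr(seq_len(nrow(lines)), function(i) {
      vals <- apply(M, 2, function(col) sbr(sp$wavelength, col, lines[i, ]))
      tibble::tibble(experiment = e, line = lines$line[i], sbr = mean(vals))
    })
  })
  di_tbl <- sbr_tbl |>
    dplyr::group_by(.data$line) |>
    dplyr::mutate(di = desirability(.data$sbr)) |>
    dplyr::ungroup()
  od_tbl <- di_tbl |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(od = overall_desirability(.data$di), .groups = "drop")
  structure(list(design = design, sbr = sbr_tbl,
                 di = dplyr::select(di_tbl, -"sbr"), od = od_tbl),
            class = "doe_result")
}

#' @export
print.doe_result <- function(x, ...) {
  cat("<doe_result>\n")
  best <- select_best(x)
  print(dplyr::left_join(x$design, x$od, by = "experiment"))
  cat(sprintf("best experiment: %d (OD = %.2f)\n", best, x$od$od[best]))
  invisible(x)
}

#' @method tidy doe_result
#' @export
tidy.doe_result <- function(x, ...) {
  dplyr::left_join(x$sbr, x$di, by = c("experiment", "line"))
}

#' @method glance doe_result
#' @export
glance.doe_result <- function(x, ...) {
  best <- select_best(x)
  tibble::tibble(n_experiments = nrow(x$od), best_experiment = best,
                 best_od = x$od$od[best])
}

#' Render synthetic spectra for a factorial design
#'
#' Test/demonstration helper: renders `replicates` spectra per experiment in
#' which all line amplitudes are scaled by a per-experiment factor
#' (`amplitude_scale`), emulating acquisition conditions of differing
#' quality. Useful for checking that desirability-based selection recovers a
#' dominant design point.
#'
#' @param amplitude_scale Numeric vector, one multiplicative factor per
#'   experiment.
#' @param lines Emission-line tibble with a `base` amplitude column, or the
#'   shipped library (default amplitudes are then used).
#' @param wavelength Wavelength grid covering the lines.
#' @param replicates Spectra per experiment.
#' @param baseline,noise_sd Continuum level and additive noise (a.u.).
#' @param seed RNG seed.
#' @return A list of per-experiment `list(wavelength, intensity)` suitable
#'   for [doe_results()].
#' @export
simulate_doe_spectra <- function(amplitude_scale, lines = emission_lines(),
                                 wavelength, replicates = 5,
                                 baseline = 50, noise_sd = 2, seed = 1) {
  if (is.null(lines$line)) lines$line <- line_id(lines)
  base <- lines[["base"]] %||% unname(default_base_intensities(lines))
  withr::with_seed(seed, {
    purrr::map(amplitude_scale, function(sc) {
      M <- sapply(seq_len(replicates), function(r) {
        render_spectrum(
          dplyr::mutate(lines, amplitude = base * sc *
                          rlnorm(nrow(lines), -0.005, 0.1)),
          wavelength, baseline = baseline, noise_sd = noise_sd)$intensity
      })
      list(wavelength = wavelength, intensity = M)
    })
  })
}
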