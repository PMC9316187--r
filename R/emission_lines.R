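#' Emission-line library
#'
#' Reads a library of atomic/ionic emission lines used both by the spectrum
#' simulator and by the signal-to-background ratio (SBR) calculation. The
#' default library shipped with the package covers the ten monitored
#' macro/micronutrient lines used for acquisition optimization (Al I 394.40,
#' C I 247.856, Ca II 393.36, Cu I 324.75, Fe II 274.64, K I 766.49,
#' Mg II 279.55, Mn II 257.61, Na I 589.59, Si I 288.15 nm) plus the further
#' lines identified in typical forage-seed LIBS spectra (additional Mg, Ca,
#' Na, K, Al, Fe transitions and the CN molecular band at 388.35 nm).
#'
#' Each line carries a peak-search window (`signal_halfwidth_nm`) and two
#' flanking background windows assumed line-free, used to estimate the
#' continuum for SBR.
#'
#' @param path Path to a line-library CSV. `NULL` (default) loads the library
#'   shipped with the package.
#' @return A tibble with columns `element`, `ionization` (`"I"` or `"II"`),
#'   `wavelength_nm`, `fwhm_nm`, `signal_halfwidth_nm`, `bg_lo_start`,
#'   `bg_lo_end`, `bg_hi_start`, `bg_hi_end` and a derived `line` identifier.
#' @export
#' @examples
#' emission_lines()
emission_lines <- function(path = NULL) {
  path <- path %||% system.file("extdata", "emission_lines.csv",
                                package = "vigorspec", mustWork = TRUE)
  lines <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_emission_lines(lines)
  lines$line <- line_id(lines)
  tibble::as_tibble(lines)
}

#' Validate an emission-line table
#'
#' Checks the structural invariants of a line library: positive widths,
#' background windows that are well-formed and do not overlap the signal
#' window, and ionization stages restricted to I/II.
#'
#' @param lines A line-library tibble (see [emission_lines()]).
#' @return The input, invisibly; errors describe the first violation found.
#' @export
validate_emission_lines <- function(lines) {
  required <- c("element", "ionization", "wavelength_nm", "fwhm_nm",
                "signal_halfwidth_nm", "bg_lo_start", "bg_lo_end",
                "bg_hi_start", "bg_hi_end")
  missing <- setdiff(required, names(lines))
  if (length(missing)) {
    abort(paste0("line library missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(lines$ionization %in% c("I", "II"))) {
    abort("ionization stage must be \"I\" or \"II\"")
  }
  if (any(lines$fwhm_nm <= 0) || any(lines$signal_halfwidth_nm <= 0)) {
    abort("line widths must be positive")
  }
  bad_bg <- lines$bg_lo_start >= lines$bg_lo_end | lines$bg_hi_start >= lines$bg_hi_end
  if (any(bad_bg)) abort("background windows must have start < end")
  sig_lo <- lines$wavelength_nm - lines$signal_halfwidth_nm
  sig_hi <- lines$wavelength_nm + lines$signal_halfwidth_nm
  overlap <- lines$bg_lo_end > sig_lo | lines$bg_hi_start < sig_hi
  if (any(overlap)) {
    abort(paste0("background windows overlap the signal window for line(s): ",
                 paste(line_id(lines[overlap, ]), collapse = ", ")))
  }
  invisible(lines)
}

#' Write an emission-line library to CSV
#'
#' @param lines A line-library tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_emission_lines <- function(lines, path) {
  validate_emission_lines(lines)
  readr::write_csv(lines[, setdiff(names(lines), "line")], path)
  invisible(path)
}
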