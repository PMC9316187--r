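# Internal helpers shared across modules.

round_half_up <- function(x) {
  # round half away from zero (base round() rounds half to even)
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a stage seed from a master seed
#'
#' Stage seeds are computed by a stable string hash of the stage name combined
#' with the master seed, so that adding or reordering pipeline stages never
#' shifts the random stream of the other stages. The result is always a valid
#' 32-bit integer seed.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name, e.g. `"simulate"`.
#' @return A single integer seed.
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 1000003
  as.integer((abs(master_seed) * 7919 + h * 2654435.0) %% 2147483629)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(min), format(max)))
  }
  invisible(x)
}

line_id <- function(lines) {
  sprintf("%s %s %.3f", lines$element, lines$ionization, lines$wavelength_nm)
}
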