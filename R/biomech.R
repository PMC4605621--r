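#' Vocal-fold string model: fundamental frequency
#'
#' Treats the vibrating fold as a simple string: `F0 = (1/2L) * sqrt(sigma / rho)`
#' with fold length `L` (m), applied tissue stress `sigma` (Pa) and tissue
#' density `rho` (kg/m^3). Constructor-style unit arguments accept the values
#' as usually reported for vocal fold tissue (mm, kPa, g/cm^3); everything is
#' normalized to SI internally.
#'
#' @param length_m Vocal fold length in metres (or use `length_mm`).
#' @param stress_pa Tissue stress in pascal (or use `stress_kpa`).
#' @param density_kg_m3 Tissue density in kg/m^3 (default 1020, i.e. 1.02 g/cm^3).
#' @param length_mm,stress_kpa,density_g_cm3 Unit-tagged alternatives.
#' @return Fundamental frequency in Hz.
#' @examples
#' string_f0(length_mm = 7.9, stress_kpa = 430.3) # ~1300 Hz
#' @export
string_f0 <- function(length_m = NULL, stress_pa = NULL,
                      density_kg_m3 = 1020,
                      length_mm = NULL, stress_kpa = NULL,
                      density_g_cm3 = NULL) {
  L <- resolve_unit(length_m, length_mm, 1e-3, "vocal fold length")
  sigma <- resolve_unit(stress_pa, stress_kpa, 1e3, "stress")
  rho <- if (!is.null(density_g_cm3)) density_g_cm3 * 1000 else density_kg_m3
  if (L <= 0) stop("vocal fold length must be positive")
  if (rho <= 0) stop("tissue density must be positive")
  if (sigma < 0) stop("stress must be non-negative")
  (1 / (2 * L)) * sqrt(sigma / rho)
}

#' Vocal-fold string model: stress required for a given F0
#'
#' Exact inversion of [string_f0()]: `sigma = rho * (2 * L * f0)^2`.
#'
#' @param f0 Fundamental frequency in Hz.
#' @inheritParams string_f0
#' @return Stress in pascal. Divide by 1000 for kPa.
#' @examples
#' string_stress(1300, length_mm = 7.9) / 1000 # ~430.3 kPa
#' @export
string_stress <- function(f0, length_m = NULL, density_kg_m3 = 1020,
                          length_mm = NULL, density_g_cm3 = NULL) {
  L <- resolve_unit(length_m, length_mm, 1e-3, "vocal fold length")
  rho <- if (!is.null(density_g_cm3)) density_g_cm3 * 1000 else density_kg_m3
  if (L <= 0) stop("vocal fold length must be positive")
  if (f0 < 0) stop("f0 must be non-negative")
  rho * (2 * L * f0)^2
}

#' Estimated vocal tract length from formant spacing
#'
#' Under a uniform quarter-wave (closed-open) tube model the formant spacing
#' `delta_f` relates to tract length as `eVTL = c / (2 * delta_f)`.
#'
#' @param delta_f Formant spacing in Hz.
#' @param c Speed of sound in warm air, m/s (default 350).
#' @return Estimated vocal tract length in metres.
#' @examples
#' estimate_vtl(423.5) * 100 # ~41.3 cm
#' @export
estimate_vtl <- function(delta_f, c = 350) {
  if (any(delta_f <= 0)) stop("delta_f must be positive")
  if (c <= 0) stop("speed of sound must be positive")
  c / (2 * delta_f)
}

#' Uniform-tube formant prediction
#'
#' Formants of a uniform tube closed at one end lie at odd multiples of
#' `delta_f / 2`: `F_i = (2i - 1) * delta_f / 2`.
#'
#' @param delta_f Formant spacing in Hz.
#' @param n Number of formants to predict.
#' @return Numeric vector `F1..Fn` in Hz.
#' @export
tube_formants <- function(delta_f, n = 6) {
  if (delta_f <= 0) stop("delta_f must be positive")
  if (n < 1) stop("n must be >= 1")
  (2 * seq_len(n) - 1) * delta_f / 2
}

resolve_unit <- function(si, tagged, factor, what) {
  if (!is.null(si) && !is.null(tagged)) {
    stop("give ", what, " in exactly one unit system")
  }
  if (!is.null(tagged)) return(tagged * factor)
  if (is.null(si)) stop(what, " is required")
  si
}
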