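#' Simulate a two-state thermal unfolding trace
#'
#' Generates a nanoDSF-style fluorescence-ratio melt curve from a two-state
#' van't Hoff model. The unfolded fraction is
#' \deqn{\theta(T) = 1 / (1 + \exp[(\Delta H / R)(1/T - 1/T_m)])}
#' with temperatures in kelvin, and the observed ratio interpolates between
#' linear native and unfolded baselines:
#' `ratio = (1 - theta) * (n0 + n1 T) + theta * (u0 + u1 T)`.
#'
#' @param tm Apparent melting temperature, degrees C (values within the
#'   scanned range are recommended).
#' @param vanthoff_dH Van't Hoff unfolding enthalpy, kJ/mol; > 0. The default
#'   400 gives a transition 10-90 percent width of roughly 10 degrees C, as
#'   typical for detergent-solubilised carrier proteins.
#' @param baselines Numeric length-4 vector `(n0, n1, u0, u1)`: intercepts
#'   and slopes (per degree C) of the native and unfolded baselines.
#' @param noise_sd Gaussian noise standard deviation on the ratio (default 0).
#' @param temperatures Scan grid, degrees C (default 25-95 in 0.1 steps,
#'   emulating a 4 C/min ramp).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `temperature_C`, `ratio`.
#' @examples
#' melt <- simulate_melt_curve(tm = 51)
#' compute_tm(melt)$tm
#' @export
simulate_melt_curve <- function(tm, vanthoff_dH = 400,
                                baselines = c(0.8, 0, 1.0, 0),
                                noise_sd = 0,
                                temperatures = seq(25, 95, by = 0.1),
                                seed = NULL) {
  assert_scalar_num(tm, "tm")
  assert_scalar_num(vanthoff_dH, "vanthoff_dH")
  if (vanthoff_dH <= 0) stop_input("`vanthoff_dH` must be > 0.")
  if (!is.numeric(baselines) || length(baselines) != 4L) {
    stop_input("`baselines` must be a numeric vector (n0, n1, u0, u1).")
  }
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  t_k <- temperatures + 273.15
  tm_k <- tm + 273.15
  theta <- 1 / (1 + exp((vanthoff_dH / .R_GAS) * (1 / t_k - 1 / tm_k)))
  native <- baselines[1] + baselines[2] * temperatures
  unfolded <- baselines[3] + baselines[4] * temperatures
  ratio <- (1 - theta) * native + theta * unfolded
  if (noise_sd > 0) ratio <- ratio + rnorm(length(ratio), sd = noise_sd)
  tibble::tibble(temperature_C = temperatures, ratio = ratio)
}

#' Simulate a size-exclusion chromatogram
#'
#' Builds an absorbance trace as a sum of Gaussian peaks on a uniform
#' elution-volume grid, with optional Gaussian noise. Used as a fixture for
#' the SEC peak-picking and calibration pipeline.
#'
#' @param peaks A data frame with columns `volume_mL` (peak centre),
#'   `height`, `width_mL` (Gaussian sd). Zero rows give a flat zero trace.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param volumes Elution-volume grid, mL (default 0-24 in 0.02 steps,
#'   spanning a 10/300 column).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `volume_mL`, `absorbance`.
#' @export
simulate_chromatogram <- function(peaks, noise_sd = 0,
                                  volumes = seq(0, 24, by = 0.02),
                                  seed = NULL) {
  if (nrow(peaks)) assert_cols(peaks, c("volume_mL", "height", "width_mL"), "peaks")
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  absorbance <- numeric(length(volumes))
  for (i in seq_len(nrow(peaks))) {
    absorbance <- absorbance + peaks$height[i] *
      exp(-0.5 * ((volumes - peaks$volume_mL[i]) / peaks$width_mL[i])^2)
  }
  if (noise_sd > 0) absorbance <- absorbance + rnorm(length(volumes), sd = noise_sd)
  tibble::tibble(volume_mL = volumes, absorbance = absorbance)
}
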