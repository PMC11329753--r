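#' Calibrate a size-exclusion column from molecular-weight standards
#'
#' Fits the standard linear relation between log10 molecular weight and the
#' partition coefficient \eqn{K_{av} = (V_e - V_0)/(V_t - V_0)}. When the
#' void (`v0`) and total (`vt`) column volumes are unknown, set them to `NA`
#' and the line is fitted on raw elution volume instead (the calibration is
#' then column-specific but equally usable for interpolation).
#'
#' @param standards Data frame with columns `mw_kDa` and `elution_volume_mL`
#'   (optionally `name`); at least two standards with distinct volumes, and
#'   larger species must elute earlier.
#' @param v0 Void volume, mL (default 8.0, typical for a 10/300 column).
#' @param vt Total column volume, mL (default 24.0).
#'
#' @return An object of class `sec_calibration`: `slope`, `intercept`
#'   (of log10(MW) on Kav or Ve), `v0`, `vt`, `use_kav`, `r_squared`,
#'   `standards`. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' std <- tibble::tibble(
#'   name = c("ferritin", "aldolase", "conalbumin", "ovalbumin"),
#'   mw_kDa = c(440, 158, 76, 43),
#'   elution_volume_mL = c(10.5, 12.5, 13.9, 15.0))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, v0 = 8.0, vt = 24.0) {
  assert_cols(standards, c("mw_kDa", "elution_volume_mL"), "standards")
  mw <- standards$mw_kDa
  ve <- standards$elution_volume_mL
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop_input("Standard molecular weights must be positive.")
  }
  if (nrow(standards) < 2L || anyDuplicated(ve)) {
    stop_input("At least two standards with distinct elution volumes are required.")
  }
  ord <- order(ve)
  if (any(diff(mw[ord]) >= 0)) {
    stop_input("Standards are not monotone: larger species must elute earlier.")
  }
  use_kav <- !is.na(v0) && !is.na(vt)
  if (use_kav) {
    if (vt <= v0) stop_input("`vt` must exceed `v0`.")
    if (any(ve <= v0) || any(ve >= vt)) {
      stop_input("Standard elution volumes must lie within (v0, vt).")
    }
    x <- (ve - v0) / (vt - v0)
  } else {
    x <- ve
  }
  fit <- lm(log10(mw) ~ x)
  cf <- coef(fit)
  if (cf[2] >= 0) stop_input("Calibration slope must be negative.")
  # suppressed: summary.lm warns on the (desirable) perfect-fit case
  r2 <- if (nrow(standards) > 2L) {
    suppressWarnings(summary(fit)$r.squared)
  } else {
    1
  }
  structure(
    list(slope = unname(cf[2]), intercept = unname(cf[1]),
         v0 = v0, vt = vt, use_kav = use_kav, r_squared = r2,
         standards = tibble::as_tibble(standards)),
    class = "sec_calibration"
  )
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat("<sec_calibration>\n")
  cat(sprintf("  log10(MW) = %.4g %+.4g * %s  (R^2 = %.4f)\n",
              x$intercept, x$slope, if (x$use_kav) "Kav" else "Ve", x$r_squared))
  if (x$use_kav) cat(sprintf("  V0 = %g mL, Vt = %g mL\n", x$v0, x$vt))
  invisible(x)
}

#' Apparent molecular weight from an elution volume
#'
#' Inverts the calibration line: `10^(slope * Kav + intercept)` (or on raw
#' Ve for calibrations without column volumes). Elution volumes outside the
#' calibrated column range are extrapolations and raise a warning.
#'
#' @param curve A `sec_calibration` from [fit_calibration()].
#' @param ve Elution volume(s), mL.
#'
#' @return Numeric vector of apparent molecular weights, kDa.
#' @export
apparent_mw <- function(curve, ve) {
  if (!inherits(curve, "sec_calibration")) {
    stop_input("`curve` must be a sec_calibration.")
  }
  if (!is.numeric(ve) || any(!is.finite(ve))) stop_input("`ve` must be numeric.")
  if (curve$use_kav) {
    if (any(ve <= curve$v0) || any(ve >= curve$vt)) {
      warn("Elution volume outside (V0, Vt); apparent MW is an extrapolation.")
    }
    x <- (ve - curve$v0) / (curve$vt - curve$v0)
  } else {
    rng <- range(curve$standards$elution_volume_mL)
    if (any(ve < rng[1]) || any(ve > rng[2])) {
      warn("Elution volume outside the standard range; apparent MW is an extrapolation.")
    }
    x <- ve
  }
  10^(curve$slope * x + curve$intercept)
}

#' Oligomeric-state call from an apparent molecular weight
#'
#' Corrects the apparent (protein + micelle) molecular weight for the bound
#' lipid/detergent micelle, divides by the protomer mass, and rounds to the
#' nearest integer copy number. The default micelle mass of 135 kDa is
#' appropriate for carriers purified in lauryl maltose neopentyl
#' glycol/cardiolipin; override it for other detergent systems. Calls whose
#' corrected-to-protomer ratio lies more than 0.3 from the nearest integer
#' are flagged ambiguous.
#'
#' @param apparent_mw Apparent molecular weight from SEC, kDa.
#' @param protomer_mw Sequence-based protomer mass, kDa; > 0.
#' @param micelle_mass Bound lipid/detergent mass, kDa (default 135).
#'
#' @return A one-row tibble of class `sec_result`: `apparent_mw_kDa`,
#'   `micelle_mass_kDa`, `corrected_mw_kDa`, `protomer_mw_kDa`, `ratio`,
#'   `oligomer_n`, `call`, `ambiguous`.
#' @examples
#' oligomeric_state(165, protomer_mw = 33)  # corrected 30 kDa -> monomer
#' @export
oligomeric_state <- function(apparent_mw, protomer_mw, micelle_mass = 135) {
  assert_scalar_num(apparent_mw, "apparent_mw")
  assert_scalar_num(protomer_mw, "protomer_mw")
  assert_scalar_num(micelle_mass, "micelle_mass", lower = 0)
  if (protomer_mw <= 0) stop_input("`protomer_mw` must be > 0.")
  corrected <- apparent_mw - micelle_mass
  if (corrected <= 0) {
    stop_input("Micelle mass (%g kDa) exceeds the apparent mass (%g kDa).",
               micelle_mass, apparent_mw)
  }
  ratio <- corrected / protomer_mw
  n <- max(1L, as.integer(round(ratio)))
  names_n <- c("monomer", "dimer", "trimer", "tetramer", "pentamer", "hexamer")
  call <- if (n <= length(names_n)) names_n[n] else sprintf("%d-mer", n)
  out <- tibble::tibble(
    apparent_mw_kDa = apparent_mw,
    micelle_mass_kDa = micelle_mass,
    corrected_mw_kDa = corrected,
    protomer_mw_kDa = protomer_mw,
    ratio = ratio,
    oligomer_n = n,
    call = call,
    ambiguous = abs(ratio - n) > 0.3
  )
  class(out) <- c("sec_result", class(out))
  out
}

#' Peak elution volume of a chromatogram
#'
#' The peak position is taken as the argmax of the absorbance trace,
#' optionally restricted to a user window.
#'
#' @param chromatogram Tibble with columns `volume_mL`, `absorbance`.
#' @param window Optional numeric length-2 `(min, max)` volume window, mL.
#'
#' @return Peak elution volume, mL.
#' @export
peak_elution_volume <- function(chromatogram, window = NULL) {
  assert_cols(chromatogram, c("volume_mL", "absorbance"), "chromatogram")
  d <- chromatogram
  if (!is.null(window)) {
    if (!is.numeric(window) || length(window) != 2L) {
      stop_input("`window` must be numeric length 2.")
    }
    d <- dplyr::filter(d, .data$volume_mL >= window[1],
                       .data$volume_mL <= window[2])
    if (!nrow(d)) stop_input("No chromatogram points inside `window`.")
  }
  d$volume_mL[which.max(d$absorbance)]
}

#' Read SEC input CSVs
#'
#' `read_chromatogram_csv()` expects columns `volume_mL, absorbance`;
#' `read_standards_csv()` expects `name, mw_kDa, elution_volume_mL`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_chromatogram_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    volume_mL = readr::col_double(),
    absorbance = readr::col_double()
  ))
}

#' @rdname read_chromatogram_csv
#' @export
read_standards_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(),
    mw_kDa = readr::col_double(),
    elution_volume_mL = readr::col_double()
  ))
}
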