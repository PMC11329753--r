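#' Tidy an exchange-curve fit
#'
#' @param x An `exchange_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.exchange_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$se[names(x$estimate)])
  )
}

#' @rdname tidy.exchange_fit
#' @export
glance.exchange_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = x$converged, flag = x$flag)
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with `term`, `estimate`,
#'   `std.error`; `glance()`: one row of fit summaries including the
#'   Km/Vmax ratio.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("km", "vmax"),
    estimate = c(x$km, x$vmax),
    std.error = c(x$se_km, x$se_vmax)
  )
}

#' @rdname tidy.mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    internal_conc_uM = x$internal_conc_uM,
    km_uM = x$km, vmax = x$vmax,
    ratio_km_vmax = x$km / x$vmax,
    rss = x$rss, n = x$n, converged = x$converged, flag = x$flag,
    weighting = x$weighting
  )
}

#' Tidy a mechanism verdict
#'
#' @param x A `mechanism_verdict`.
#' @param ... Unused.
#' @return `tidy()`: one row per sub-test with its statistic, degrees of
#'   freedom, p-value, and call; `glance()`: a one-row summary with the
#'   combined call.
#' @export
tidy.mechanism_verdict <- function(x, ...) {
  tibble::tibble(
    test = c("ratio_constancy", "global_fit"),
    statistic = c(x$ratio_test$statistic, x$global_fit$statistic),
    df = c(paste(x$ratio_test$df, collapse = ","),
           paste(x$global_fit$df, collapse = ",")),
    p.value = c(x$ratio_test$p_value, x$global_fit$p_value),
    call = c(x$ratio_test$call, x$global_fit$call)
  )
}

#' @rdname tidy.mechanism_verdict
#' @export
glance.mechanism_verdict <- function(x, ...) {
  tibble::tibble(
    call = x$call, alpha = x$alpha,
    ratio_p = x$ratio_test$p_value,
    global_fit_p = x$global_fit$p_value
  )
}

#' Summarise a melting-temperature result
#'
#' @param x A `tm_result`.
#' @param ... Unused.
#' @return A one-row tibble with `tm_C`, `prominence`, `n_peaks`, `quality`.
#' @export
glance.tm_result <- function(x, ...) {
  tibble::tibble(tm_C = x$tm, prominence = x$prominence,
                 n_peaks = nrow(x$peaks), quality = x$quality)
}

#' Tidy a SEC calibration
#'
#' @param x A `sec_calibration`.
#' @param ... Unused.
#' @return `tidy()`: the standards with fitted Kav and predicted MW;
#'   `glance()`: slope, intercept, and goodness of fit.
#' @export
tidy.sec_calibration <- function(x, ...) {
  std <- x$standards
  pred <- apparent_mw(x, std$elution_volume_mL)
  out <- tibble::tibble(
    mw_kDa = std$mw_kDa,
    elution_volume_mL = std$elution_volume_mL,
    predicted_mw_kDa = pred
  )
  if ("name" %in% names(std)) out <- dplyr::bind_cols(name = std$name, out)
  if (x$use_kav) {
    out$kav <- (std$elution_volume_mL - x$v0) / (x$vt - x$v0)
  }
  out
}

#' @rdname tidy.sec_calibration
#' @export
glance.sec_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, use_kav = x$use_kav,
                 v0 = x$v0, vt = x$vt, n_standards = nrow(x$standards))
}
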