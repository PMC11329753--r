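#' Plot uptake curves from a plate of measurements
#'
#' One panel per condition, points per replicate; background conditions are
#' drawn in grey.
#'
#' @param data Plate-format tibble.
#' @return A ggplot object.
#' @export
plot_uptake_curves <- function(data) {
  assert_cols(data, c("time_s", "quantity_nmol_per_mg", "replicate",
                      "internal_conc_uM", "external_conc_uM"))
  data <- dplyr::mutate(
    data,
    panel = sprintf("int %g / ext %g uM", .data$internal_conc_uM,
                    .data$external_conc_uM)
  )
  ggplot2::ggplot(data, ggplot2::aes(.data$time_s, .data$quantity_nmol_per_mg,
                                     group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Uptake (nmol/mg)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.exchange_fit <- function(object, ...) {
  grid <- tibble::tibble(time_s = seq(min(object$data$time_s),
                                      max(object$data$time_s), length.out = 200))
  grid$fit <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$time_s, .data$quantity_nmol_per_mg)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$time_s, .data$fit),
                       colour = "firebrick") +
    ggplot2::labs(
      x = "Time (s)", y = "Uptake (nmol/mg)",
      subtitle = sprintf("beta = %.3g nmol/mg, k = %.3g nmol mg^-1 min^-1, d = %.2g s",
                         object$estimate["beta"], object$estimate["k"],
                         object$estimate["d"])
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mm_fit <- function(object, ...) {
  d <- object$data
  s <- seq(0, max(d$external_conc_uM), length.out = 150)
  curve <- tibble::tibble(external_conc_uM = s,
                          rate_nmol_mg_min = object$vmax * s / (object$km + s))
  ggplot2::ggplot(d, ggplot2::aes(.data$external_conc_uM,
                                  .data$rate_nmol_mg_min)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(
      x = "External substrate (uM)", y = "Initial rate (nmol mg^-1 min^-1)",
      subtitle = sprintf("Km = %.3g uM, Vmax = %.3g nmol mg^-1 min^-1",
                         object$km, object$vmax)
    ) +
    ggplot2::theme_minimal()
}

#' Michaelis-Menten plot for a set of rate series
#'
#' Initial rates (with replicate-SD error bars) against external substrate
#' concentration, one colour per internal concentration, overlaid with the
#' fitted hyperbolae.
#'
#' @param kmvmax A `kmvmax_set` from [fit_mm_curves()].
#' @return A ggplot object.
#' @export
plot_michaelis_menten <- function(kmvmax) {
  if (!inherits(kmvmax, "kmvmax_set")) stop_input("`kmvmax` must be a kmvmax_set.")
  pts <- purrr::map(kmvmax$fit, function(f) {
    d <- f$data
    d$internal_conc_uM <- f$internal_conc_uM
    d
  }) |> dplyr::bind_rows()
  curves <- purrr::map(kmvmax$fit, function(f) {
    s <- seq(0, max(f$data$external_conc_uM), length.out = 150)
    tibble::tibble(internal_conc_uM = f$internal_conc_uM,
                   external_conc_uM = s,
                   rate_nmol_mg_min = f$vmax * s / (f$km + s))
  }) |> dplyr::bind_rows()
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$external_conc_uM,
                                         .data$rate_nmol_mg_min,
                                         colour = factor(.data$internal_conc_uM))) +
    ggplot2::geom_point()
  if ("rate_sd" %in% names(pts)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate_nmol_mg_min - .data$rate_sd,
                   ymax = .data$rate_nmol_mg_min + .data$rate_sd),
      width = 0)
  }
  p + ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = "External substrate (uM)",
                  y = "Initial rate (nmol mg^-1 min^-1)",
                  colour = "Internal (uM)") +
    ggplot2::theme_minimal()
}

#' Lineweaver-Burk plot from iterative fits
#'
#' Double-reciprocal points with lines derived from the nonlinear fits
#' (see [lineweaver_burk()]); parallel lines indicate a ping-pong mechanism.
#'
#' @param x A `kmvmax_set`, `mm_fit`, or `lb_transform`.
#' @return A ggplot object.
#' @export
plot_lineweaver_burk <- function(x) {
  lb <- if (inherits(x, "lb_transform")) x else lineweaver_burk(x)
  ggplot2::ggplot(lb$points, ggplot2::aes(.data$inv_s, .data$inv_v,
                                          colour = factor(.data$internal_conc_uM))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lb$lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = factor(.data$internal_conc_uM))
    ) +
    ggplot2::labs(x = "1/[S] (uM^-1)", y = "1/v (mg min nmol^-1)",
                  colour = "Internal (uM)") +
    ggplot2::theme_minimal()
}

#' Km against Vmax across internal concentrations
#'
#' The discrimination plot: under a ping-pong mechanism the points fall on a
#' line through the origin (constant Km/Vmax); under a sequential mechanism
#' the ratio falls as the internal concentration rises.
#'
#' @param kmvmax A `kmvmax_set` from [fit_mm_curves()].
#' @return A ggplot object.
#' @export
plot_km_vmax <- function(kmvmax) {
  if (!inherits(kmvmax, "kmvmax_set")) stop_input("`kmvmax` must be a kmvmax_set.")
  ratios <- km_vmax_ratios(kmvmax)
  rbar <- sum(ratios$ratio / pmax(ratios$ratio_se, 1e-12)^2) /
    sum(1 / pmax(ratios$ratio_se, 1e-12)^2)
  ggplot2::ggplot(kmvmax, ggplot2::aes(.data$vmax, .data$km_uM,
                                       colour = factor(.data$internal_conc_uM))) +
    ggplot2::geom_abline(slope = rbar, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$km_uM - .data$km_se,
                                        ymax = .data$km_uM + .data$km_se),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$vmax - .data$vmax_se,
                                         xmax = .data$vmax + .data$vmax_se),
                            height = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::expand_limits(x = 0, y = 0) +
    ggplot2::labs(x = "Vmax (nmol mg^-1 min^-1)", y = "Km (uM)",
                  colour = "Internal (uM)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tm_result <- function(object, ...) {
  ggplot2::ggplot(object$derivative,
                  ggplot2::aes(.data$temperature_C, .data$dR_dT)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tm, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "Temperature (C)", y = "dR/dT",
                  subtitle = sprintf("Tm = %.1f C (%s)", object$tm,
                                     object$quality)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sec_calibration <- function(object, ...) {
  std <- tidy(object)
  xvar <- if (object$use_kav) "kav" else "elution_volume_mL"
  ggplot2::ggplot(std, ggplot2::aes(.data[[xvar]], log10(.data$mw_kDa))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = if (object$use_kav) "Kav" else "Elution volume (mL)",
                  y = "log10 MW (kDa)") +
    ggplot2::theme_minimal()
}

#' Plot a chromatogram
#'
#' @param chromatogram Tibble with `volume_mL`, `absorbance`.
#' @return A ggplot object.
#' @export
plot_chromatogram <- function(chromatogram) {
  assert_cols(chromatogram, c("volume_mL", "absorbance"), "chromatogram")
  ggplot2::ggplot(chromatogram, ggplot2::aes(.data$volume_mL, .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Elution volume (mL)", y = "Absorbance (a.u.)") +
    ggplot2::theme_minimal()
}
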