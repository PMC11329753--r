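mm_residuals <- function(par, s, v, w) {
  sqrt(w) * (par[["vmax"]] * s / (par[["km"]] + s) - v)
}

mm_jacobian <- function(par, s, v, w) {
  den <- par[["km"]] + s
  cbind(km = -sqrt(w) * par[["vmax"]] * s / den^2,
        vmax = sqrt(w) * s / den)
}

#' Fit apparent Michaelis-Menten parameters to an initial-rate series
#'
#' Iterative (Levenberg-Marquardt) nonlinear least squares of
#' \eqn{v = V_{max} S / (K_m + S)} on an external-concentration rate series,
#' optionally weighted by inverse replicate variance. Starting values are
#' `vmax = 1.1 max(v)` and `km` = S at half-maximal rate. A fit whose Km
#' exceeds ten times the largest tested concentration, or which fails to
#' converge, is flagged `"poorly_determined"`.
#'
#' @param rates Tibble with columns `external_conc_uM`, `rate_nmol_mg_min`,
#'   and optionally `rate_sd` (used by inverse-variance weighting) and
#'   `internal_conc_uM` (recorded as the series tag). At least 4 distinct
#'   external concentrations are required.
#' @param weighting `"none"` (default) or `"inverse_variance"` (weights
#'   `1/rate_sd^2`; falls back to unweighted when replicate SDs are missing
#'   or zero). With the few replicates typical of plate assays, per-point
#'   SDs are themselves noisy, and unweighted fitting gives better
#'   calibrated standard errors; inverse-variance weighting is worthwhile
#'   when replicate counts are large.
#' @param internal_conc Optional numeric tag overriding the
#'   `internal_conc_uM` column.
#'
#' @return An object of class `mm_fit`: `km`, `vmax`, `se_km`, `se_vmax`,
#'   `cov_km_vmax`, `internal_conc_uM`, `rss`, `n`, `converged`, `flag`,
#'   `weighting`, `data`. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' s <- c(0.5, 1, 1.5, 2.5, 5, 10, 15, 20)
#' rates <- tibble::tibble(external_conc_uM = s,
#'                         rate_nmol_mg_min = 100 * s / (5 + s))
#' tidy(fit_michaelis_menten(rates))
#' @export
fit_michaelis_menten <- function(rates,
                                 weighting = c("none", "inverse_variance"),
                                 internal_conc = NULL) {
  assert_cols(rates, c("external_conc_uM", "rate_nmol_mg_min"), "rates")
  weighting <- match.arg(weighting)
  s <- rates$external_conc_uM
  v <- rates$rate_nmol_mg_min
  keep <- is.finite(s) & is.finite(v)
  if (any(!keep)) {
    inform(sprintf("Dropping %d non-finite rate point(s).", sum(!keep)))
  }
  s <- s[keep]; v <- v[keep]
  if (length(unique(s)) < 4L) {
    stop_input("At least 4 distinct external concentrations are required.")
  }
  internal_conc <- internal_conc %||%
    (if ("internal_conc_uM" %in% names(rates)) rates$internal_conc_uM[1] else NA_real_)

  w <- rep(1, length(s))
  used_weighting <- "none"
  if (weighting == "inverse_variance" && "rate_sd" %in% names(rates)) {
    sds <- rates$rate_sd[keep]
    if (all(is.finite(sds)) && all(sds > 0)) {
      w <- 1 / sds^2
      used_weighting <- "inverse_variance"
    }
  }

  vmax0 <- 1.1 * max(v)
  km0 <- s[which.min(abs(v - max(v) / 2))]
  if (km0 <= 0) km0 <- median(s)
  par0 <- c(km = km0, vmax = vmax0)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, lower = c(km = 1e-12, vmax = 1e-12),
      fn = mm_residuals, jac = mm_jacobian, s = s, v = v, w = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$info %in% 1:4
  if (!converged) {
    return(structure(
      list(km = NA_real_, vmax = NA_real_, se_km = Inf, se_vmax = Inf,
           cov_km_vmax = NA_real_, internal_conc_uM = internal_conc,
           rss = NA_real_, n = length(s), converged = FALSE,
           flag = "poorly_determined", weighting = used_weighting,
           data = rates[keep, ]),
      class = "mm_fit"
    ))
  }
  est <- fit$par
  rss <- sum(fit$fvec^2)
  jac <- mm_jacobian(est, s, v, w)
  covm <- tryCatch({
    sigma2 <- rss / (length(s) - 2L)
    sigma2 * solve(crossprod(jac))
  }, error = function(e) matrix(c(Inf, NA, NA, Inf), 2,
                                dimnames = list(c("km", "vmax"), c("km", "vmax"))))
  flag <- if (est[["km"]] > 10 * max(s)) "poorly_determined" else "ok"
  structure(
    list(km = est[["km"]], vmax = est[["vmax"]],
         se_km = sqrt(max(covm["km", "km"], 0)),
         se_vmax = sqrt(max(covm["vmax", "vmax"], 0)),
         cov_km_vmax = covm["km", "vmax"],
         internal_conc_uM = internal_conc, rss = rss, n = length(s),
         converged = TRUE, flag = flag, weighting = used_weighting,
         data = rates[keep, ]),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>", x$flag, "\n")
  if (!is.na(x$internal_conc_uM)) {
    cat(sprintf("  internal substrate: %g uM\n", x$internal_conc_uM))
  }
  cat(sprintf("  Km   = %.4g +/- %.3g uM\n", x$km, x$se_km))
  cat(sprintf("  Vmax = %.4g +/- %.3g nmol mg^-1 min^-1\n", x$vmax, x$se_vmax))
  cat(sprintf("  Km/Vmax = %.4g (weighting: %s)\n", x$km / x$vmax, x$weighting))
  invisible(x)
}

#' Fit Michaelis-Menten curves for every internal concentration
#'
#' Splits an initial-rate table by internal substrate concentration and fits
#' each series with [fit_michaelis_menten()], returning the set of apparent
#' (Km, Vmax) pairs used by the mechanism-discrimination tests.
#'
#' All series in one experiment share the same measurement process, so by
#' default their residual variances are pooled (`pool_variance = TRUE`):
#' each fit's covariance is rescaled to a common residual variance estimated
#' on the summed degrees of freedom. With only a handful of points per
#' series this substantially stabilises the standard errors that the
#' ratio-constancy homogeneity test divides by, keeping that test close to
#' its nominal size.
#'
#' @param rates An initial-rate table from [initial_rates_table()] (any
#'   background rows, `internal_conc_uM == 0`, are ignored).
#' @param pool_variance Pool the residual variance across series when
#'   rescaling fit covariances (default `TRUE`).
#' @inheritParams fit_michaelis_menten
#'
#' @return A tibble of class `kmvmax_set`, one row per internal
#'   concentration: `internal_conc_uM`, `km_uM`, `km_se`, `vmax`, `vmax_se`,
#'   `cov_km_vmax`, `ratio_km_vmax`, `flag`, and a list-column `fit` of
#'   `mm_fit` objects.
#' @export
fit_mm_curves <- function(rates, weighting = c("none", "inverse_variance"),
                          pool_variance = TRUE) {
  assert_cols(rates, c("internal_conc_uM", "external_conc_uM",
                       "rate_nmol_mg_min"), "rates")
  weighting <- match.arg(weighting)
  rates <- dplyr::filter(rates, .data$internal_conc_uM > 0)
  if (!nrow(rates)) stop_input("No non-background rate series to fit.")
  fits <- unname(purrr::map(split(rates, rates$internal_conc_uM),
                            fit_michaelis_menten, weighting = weighting))
  if (pool_variance && length(fits) > 1L &&
      all(purrr::map_lgl(fits, "converged"))) {
    rss <- sum(purrr::map_dbl(fits, "rss"))
    dfs <- sum(purrr::map_dbl(fits, ~ .x$n - 2))
    pooled <- rss / dfs
    fits <- purrr::map(fits, function(f) {
      own <- f$rss / (f$n - 2)
      if (own > 0 && is.finite(own) && pooled > 0) {
        scale <- pooled / own
        f$se_km <- f$se_km * sqrt(scale)
        f$se_vmax <- f$se_vmax * sqrt(scale)
        f$cov_km_vmax <- f$cov_km_vmax * scale
      }
      f
    })
  }
  out <- tibble::tibble(
    internal_conc_uM = purrr::map_dbl(fits, "internal_conc_uM"),
    km_uM = purrr::map_dbl(fits, "km"),
    km_se = purrr::map_dbl(fits, "se_km"),
    vmax = purrr::map_dbl(fits, "vmax"),
    vmax_se = purrr::map_dbl(fits, "se_vmax"),
    cov_km_vmax = purrr::map_dbl(fits, "cov_km_vmax"),
    ratio_km_vmax = purrr::map_dbl(fits, ~ .x$km / .x$vmax),
    flag = purrr::map_chr(fits, "flag"),
    fit = unname(fits)
  ) |> dplyr::arrange(.data$internal_conc_uM)
  class(out) <- c("kmvmax_set", class(out))
  out
}

#' Write a kinetic-parameters table to CSV
#'
#' @param kmvmax A `kmvmax_set` tibble from [fit_mm_curves()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(kmvmax, path) {
  ratios <- km_vmax_ratios(kmvmax)
  out <- dplyr::select(as.data.frame(kmvmax), -dplyr::any_of("fit")) |>
    dplyr::left_join(
      dplyr::select(ratios, "internal_conc_uM", ratio_se = "ratio_se"),
      by = "internal_conc_uM"
    )
  readr::write_csv(out, path)
  invisible(path)
}

#' Lineweaver-Burk transformation for visualization
#'
#' Produces double-reciprocal points `(1/S, 1/v)` together with the line
#' implied by the iterative Michaelis-Menten fit:
#' `1/v = 1/Vmax + (Km/Vmax) (1/S)`. The line is never obtained by linear
#' regression of the transformed points, whose error structure
#' over-weights the least accurate low-concentration rates; the
#' transformation is for display only. Zero or negative rates are excluded
#' with a message, and a warning is attached when any rate has a coefficient
#' of variation above 50 percent.
#'
#' @param x An `mm_fit` or a `kmvmax_set`.
#'
#' @return A list of class `lb_transform` with tibbles `points`
#'   (`internal_conc_uM`, `inv_s`, `inv_v`) and `lines`
#'   (`internal_conc_uM`, `slope`, `intercept`), plus a character vector
#'   `warnings`.
#' @export
lineweaver_burk <- function(x) {
  fits <- if (inherits(x, "mm_fit")) {
    list(x)
  } else if (inherits(x, "kmvmax_set")) {
    x$fit
  } else {
    stop_input("`x` must be an mm_fit or a kmvmax_set.")
  }
  warnings <- character()
  pts <- list(); lns <- list()
  for (f in fits) {
    d <- f$data
    bad <- d$rate_nmol_mg_min <= 0
    if (any(bad)) {
      inform(sprintf("Excluding %d non-positive rate(s) from the double-reciprocal plot.",
                     sum(bad)))
      d <- d[!bad, ]
    }
    if ("rate_sd" %in% names(d)) {
      cv <- d$rate_sd / d$rate_nmol_mg_min
      if (any(is.finite(cv) & cv > 0.5)) {
        warnings <- c(warnings, sprintf(
          "internal %g uM: rate CV exceeds 50%% at low concentrations; reciprocal points are unreliable.",
          f$internal_conc_uM))
      }
    }
    pts[[length(pts) + 1L]] <- tibble::tibble(
      internal_conc_uM = f$internal_conc_uM,
      inv_s = 1 / d$external_conc_uM,
      inv_v = 1 / d$rate_nmol_mg_min
    )
    lns[[length(lns) + 1L]] <- tibble::tibble(
      internal_conc_uM = f$internal_conc_uM,
      slope = f$km / f$vmax,
      intercept = 1 / f$vmax
    )
  }
  out <- list(points = dplyr::bind_rows(pts), lines = dplyr::bind_rows(lns),
              warnings = warnings)
  if (length(warnings)) for (w in warnings) warn(w)
  structure(out, class = "lb_transform")
}
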