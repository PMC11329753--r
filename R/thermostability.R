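# Moving-average smoother over a temperature window. The window shrinks
# symmetrically near the edges, so linear traces pass through unchanged.
smooth_window <- function(y, temps, window_C) {
  if (window_C <= 0) return(y)
  step <- median(diff(temps))
  half <- max(1L, floor(window_C / (2 * step)))
  n <- length(y)
  cs <- cumsum(c(0, y))
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }, numeric(1))
}

# Topographic prominence of local maxima of a trace: height above the key
# saddle towards higher terrain. A side without higher terrain imposes no
# saddle; the global maximum is referenced to the trace minimum.
peak_prominences <- function(d, peaks) {
  n <- length(d)
  vapply(peaks, function(i) {
    left <- if (i > 1L) d[seq_len(i - 1L)] else numeric()
    right <- if (i < n) d[seq(i + 1L, n)] else numeric()
    higher_l <- which(left > d[i])
    base_l <- if (length(higher_l)) min(left[seq(max(higher_l), i - 1L)]) else -Inf
    higher_r <- which(right > d[i])
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else -Inf
    base <- max(base_l, base_r)
    if (!is.finite(base)) base <- min(d)
    d[i] - base
  }, numeric(1))
}

#' Apparent melting temperature from an unfolding trace
#'
#' Implements the derivative-peak rule used in nanoDSF: the apparent melting
#' temperature is the temperature of the (most prominent, positive) peak in
#' the derivative dR/dT of the fluorescence-ratio unfolding curve. The ratio
#' is first smoothed with a moving average over a temperature window, the
#' derivative is taken by central differences and smoothed with the same
#' window, candidate peaks must have a topographic prominence of at least
#' 5 percent of the derivative range, and the reported Tm is refined to
#' sub-grid resolution by fitting a Gaussian peak plus constant offset to
#' the derivative over the top of the winning peak. Peaks at the edges of
#' the scan are flagged unreliable.
#'
#' @param curve Tibble with columns `temperature_C` (strictly increasing,
#'   at least 20 points) and `ratio`.
#' @param smoothing_window Moving-average window, degrees C (default 2).
#'
#' @return An object of class `tm_result`: `tm` (degrees C), `derivative`
#'   (tibble `temperature_C`, `dR_dT`), `peaks` (tibble of all qualifying
#'   peaks with prominences), `prominence` of the winning peak, `quality`
#'   (`"ok"` or `"edge_unreliable"`), `smoothing_window`. Supports
#'   [glance()] and [autoplot()].
#' @examples
#' compute_tm(simulate_melt_curve(tm = 51))$tm
#' @export
compute_tm <- function(curve, smoothing_window = 2) {
  assert_cols(curve, c("temperature_C", "ratio"), "curve")
  assert_scalar_num(smoothing_window, "smoothing_window", lower = 0)
  temps <- curve$temperature_C
  ratio <- curve$ratio
  if (length(temps) < 20L) {
    stop_input("At least 20 points are required for a melt curve.")
  }
  if (any(diff(temps) <= 0)) {
    stop_input("`temperature_C` must be strictly increasing (is the trace reversed?).")
  }
  if (any(!is.finite(ratio))) stop_input("Ratios must be finite.")
  if (diff(range(ratio)) <= 1e-10 * max(1, abs(mean(ratio)))) {
    stop_input("No unfolding transition detected (monotone or flat trace).")
  }

  sm <- smooth_window(ratio, temps, smoothing_window)
  n <- length(sm)
  d <- numeric(n)
  d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (temps[3:n] - temps[1:(n - 2)])
  d[1] <- (sm[2] - sm[1]) / (temps[2] - temps[1])
  d[n] <- (sm[n] - sm[n - 1]) / (temps[n] - temps[n - 1])
  # smooth the derivative with the same window before peak analysis
  d <- smooth_window(d, temps, smoothing_window)

  # peak analysis is restricted to the interior where the full smoothing
  # window fits; nearer the edges the shrunken windows leave the derivative
  # dominated by raw point noise
  step <- median(diff(temps))
  half_w <- max(1L, floor(smoothing_window / (2 * step)))
  lo <- min(2L * half_w + 1L, n %/% 3L)
  hi <- n - lo + 1L
  dv <- d[lo:hi]
  m <- length(dv)

  rng <- diff(range(dv))
  # a transition shows as a bump well above the baseline slope; a purely
  # linear or flat trace has a near-constant derivative
  if (rng <= 0 || rng <= 0.2 * max(abs(dv))) {
    stop_input("No unfolding transition detected (monotone or flat trace).")
  }
  is_max <- c(dv[1] >= dv[2],
              dv[2:(m - 1)] >= dv[1:(m - 2)] & dv[2:(m - 1)] >= dv[3:m],
              dv[m] >= dv[m - 1])
  cand <- which(is_max & dv > 0)
  if (!length(cand)) {
    stop_input("No unfolding transition detected (no positive derivative peak).")
  }
  prom <- peak_prominences(dv, cand)
  cand <- cand + lo - 1L  # back to full-trace indexing
  keep <- prom >= 0.05 * rng
  if (!any(keep)) {
    stop_input("No unfolding transition detected (no derivative peak with sufficient prominence).")
  }
  cand <- cand[keep]; prom <- prom[keep]
  best <- cand[which.max(prom)]

  # sub-grid refinement: fit a Gaussian peak plus constant offset to the
  # derivative over the region within 80 percent of the peak's prominence
  # (symmetrized around the maximum); the fitted centre is the reported Tm
  floor_height <- d[best] - 0.8 * prom[which.max(prom)]
  left <- best
  while (left > lo && d[left - 1L] > floor_height) left <- left - 1L
  right <- best
  while (right < hi && d[right + 1L] > floor_height) right <- right + 1L
  half <- min(best - left, right - best)
  half <- max(half, max(4L, round(smoothing_window / step)))
  idx <- max(lo, best - half):min(hi, best + half)
  tt <- temps[idx]; dd <- d[idx]
  start <- c(mu = temps[best], lw = log((tt[length(tt)] - tt[1]) / 4),
             h = d[best] - min(dd), c = min(dd))
  peak_fn <- function(p) {
    p[["c"]] + p[["h"]] * exp(-0.5 * ((tt - p[["mu"]]) / exp(p[["lw"]]))^2) - dd
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(start, fn = peak_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  tm <- temps[best]
  if (!is.null(fit) && fit$info %in% 1:4) {
    mu <- fit$par[["mu"]]
    if (is.finite(mu) && mu >= tt[1] && mu <= tt[length(tt)]) tm <- mu
  }

  edge_margin <- max(smoothing_window, 2 * step)
  quality <- if (best <= lo || best >= hi ||
                 temps[best] <= temps[1] + edge_margin ||
                 temps[best] >= temps[n] - edge_margin) {
    "edge_unreliable"
  } else {
    "ok"
  }
  structure(
    list(
      tm = tm,
      derivative = tibble::tibble(temperature_C = temps, dR_dT = d),
      peaks = tibble::tibble(temperature_C = temps[cand], dR_dT = d[cand],
                             prominence = prom),
      prominence = max(prom),
      quality = quality,
      smoothing_window = smoothing_window
    ),
    class = "tm_result"
  )
}

#' @export
print.tm_result <- function(x, ...) {
  cat("<tm_result>\n")
  cat(sprintf("  Tm = %.2f C (%s), prominence %.3g, smoothing %g C\n",
              x$tm, x$quality, x$prominence, x$smoothing_window))
  if (nrow(x$peaks) > 1L) {
    cat(sprintf("  %d qualifying derivative peaks at: %s C\n", nrow(x$peaks),
                paste(sprintf("%.1f", x$peaks$temperature_C), collapse = ", ")))
  }
  invisible(x)
}

#' Ligand-induced thermal shift
#'
#' The thermal shift is `Tm(holo) - Tm(apo)`; a positive shift indicates
#' stabilisation by the bound ligand. The sign is preserved (a destabilising
#' ligand reports a negative shift). Edge-flagged inputs propagate to
#' `reliable = FALSE`.
#'
#' @param apo,holo `tm_result` objects for the ligand-free and ligand-bound
#'   samples.
#'
#' @return A tibble with `tm_apo_C`, `tm_holo_C`, `delta_tm_C`, `reliable`.
#' @export
thermal_shift <- function(apo, holo) {
  if (!inherits(apo, "tm_result") || !inherits(holo, "tm_result")) {
    stop_input("`apo` and `holo` must be tm_result objects from compute_tm().")
  }
  tibble::tibble(
    tm_apo_C = apo$tm,
    tm_holo_C = holo$tm,
    delta_tm_C = holo$tm - apo$tm,
    reliable = apo$quality == "ok" && holo$quality == "ok"
  )
}

#' Read a melt-curve CSV
#'
#' Two-column CSV `temperature_C, ratio`.
#'
#' @param path File path.
#' @return A tibble with `temperature_C`, `ratio`.
#' @export
read_melt_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    temperature_C = readr::col_double(),
    ratio = readr::col_double()
  ))
}
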