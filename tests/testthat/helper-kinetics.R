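# Shared fixture builders (all data generated in code).

assay_times <- c(0, 10, 20, 30, 40, 50, 60, 90, 120)
assay_external <- c(0.5, 1, 1.5, 2.5, 5, 10, 15, 20)

# Exponential-exchange curve evaluated exactly (unclamped model form).
exact_exchange_curve <- function(beta, k, d = 0, times = assay_times) {
  tibble::tibble(
    time_s = times,
    quantity_nmol_per_mg = uptake_model(times, beta, k, d)
  )
}

# Noise-free config for deterministic checks.
quiet_noise <- function() {
  noise_model(counting_cv = 0, background_offset = 0, poisson_scale = 0,
              biological_cv = 0)
}

quiet_cfg <- function(...) {
  sim_config(noise = quiet_noise(), ...)
}

# Exact Michaelis-Menten rate series.
mm_series <- function(km, vmax, s = assay_external, internal = 1000) {
  tibble::tibble(
    internal_conc_uM = internal,
    external_conc_uM = s,
    rate_nmol_mg_min = vmax * s / (km + s)
  )
}

# Exhaustive lattice minimizer of the exchange-curve sum of squares.
grid_search_exchange <- function(t, q, beta_grid, k_grid, d_grid) {
  best <- list(ss = Inf)
  bk <- expand.grid(beta = beta_grid, k = k_grid)
  qmat <- matrix(q, nrow(bk), length(t), byrow = TRUE)
  for (d in d_grid) {
    u <- outer(bk$k / (60 * bk$beta), t - d)
    m <- bk$beta * (1 - exp(-u))
    ss <- rowSums((m - qmat)^2)
    i <- which.min(ss)
    if (ss[i] < best$ss) {
      best <- list(ss = ss[i], beta = bk$beta[i], k = bk$k[i], d = d)
    }
  }
  best
}

# Exhaustive lattice minimizer of the Michaelis-Menten sum of squares.
grid_search_mm <- function(s, v, km_grid, vmax_grid) {
  g <- expand.grid(km = km_grid, vmax = vmax_grid)
  ss <- numeric(nrow(g))
  for (i in seq_along(s)) {
    ss <- ss + (g$vmax * s[i] / (g$km + s[i]) - v[i])^2
  }
  i <- which.min(ss)
  list(ss = ss[i], km = g$km[i], vmax = g$vmax[i])
}
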