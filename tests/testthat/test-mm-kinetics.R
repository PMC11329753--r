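test_that("exact Michaelis-Menten data are recovered exactly", {
  rates <- mm_series(km = 5, vmax = 100)
  fit <- fit_michaelis_menten(rates)
  expect_true(fit$converged)
  expect_equal(fit$km, 5, tolerance = 1e-7)
  expect_equal(fit$vmax, 100, tolerance = 1e-7)
  # v at S = Km is half-maximal
  expect_equal(fit$vmax * fit$km / (fit$km + fit$km), fit$vmax / 2)
  expect_identical(glance(fit)$flag, "ok")
})

test_that("the fit matches an exhaustive (Km, Vmax) lattice search", {
  rates <- mm_series(km = 5, vmax = 100)
  fit <- fit_michaelis_menten(rates)
  lattice <- grid_search_mm(
    rates$external_conc_uM, rates$rate_nmol_mg_min,
    km_grid = seq(5 * 0.995, 5 * 1.005, length.out = 500),
    vmax_grid = seq(100 * 0.995, 100 * 1.005, length.out = 500)
  )
  expect_lt(abs(fit$km - lattice$km) / lattice$km, 1e-4)
  expect_lt(abs(fit$vmax - lattice$vmax) / lattice$vmax, 1e-4)
})

test_that("estimates are order-invariant and scale-equivariant", {
  rates <- mm_series(km = 3, vmax = 80)
  fit <- fit_michaelis_menten(rates)
  shuffled <- rates[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  fit_sh <- fit_michaelis_menten(shuffled)
  expect_equal(fit_sh$km, fit$km, tolerance = 1e-9)
  expect_equal(fit_sh$vmax, fit$vmax, tolerance = 1e-9)

  scaled <- dplyr::mutate(rates, rate_nmol_mg_min = 2.5 * rate_nmol_mg_min)
  fit_sc <- fit_michaelis_menten(scaled)
  expect_equal(fit_sc$vmax, 2.5 * fit$vmax, tolerance = 1e-7)
  expect_equal(fit_sc$km, fit$km, tolerance = 1e-7)
})

test_that("inverse-variance weighting is used when replicate SDs exist", {
  rates <- mm_series(km = 5, vmax = 100) |>
    dplyr::mutate(rate_sd = c(4, 4, 4, 4, 0.1, 0.1, 0.1, 0.1))
  fit_w <- fit_michaelis_menten(rates, weighting = "inverse_variance")
  expect_identical(fit_w$weighting, "inverse_variance")
  fit_u <- fit_michaelis_menten(rates, weighting = "none")
  expect_identical(fit_u$weighting, "none")
  # exact data: both weightings agree on the truth
  expect_equal(fit_w$km, fit_u$km, tolerance = 1e-6)
  # missing SDs fall back to unweighted
  rates$rate_sd[3] <- NA
  expect_identical(fit_michaelis_menten(rates)$weighting, "none")
})

test_that("Km far beyond the tested range is flagged poorly determined", {
  # near-linear data: Km >> max(S)
  s <- assay_external
  rates <- tibble::tibble(external_conc_uM = s,
                          rate_nmol_mg_min = 1000 * s / (5000 + s))
  fit <- fit_michaelis_menten(rates)
  expect_identical(fit$flag, "poorly_determined")
  expect_error(fit_michaelis_menten(mm_series(5, 100, s = c(1, 2, 3))),
               "4 distinct")
})

test_that("fit_mm_curves tags each internal concentration and its ratio", {
  p <- rate_law_params(200, 5, 200)
  app <- apparent_parameters(p, "ping_pong", c(100, 250, 500, 1000))
  rates <- purrr::pmap(app, function(internal_conc_uM, km_app_uM, vmax_app, ...) {
    mm_series(km_app_uM, vmax_app, internal = internal_conc_uM)
  }) |> dplyr::bind_rows()
  set <- fit_mm_curves(rates)
  expect_s3_class(set, "kmvmax_set")
  expect_equal(set$km_uM, app$km_app_uM, tolerance = 1e-6)
  expect_equal(set$vmax, app$vmax_app, tolerance = 1e-6)
  # the ping-pong pattern: Km and Vmax fall together, ratio constant
  expect_true(all(diff(set$km_uM) > 0))
  expect_true(all(diff(set$vmax) > 0))
  expect_equal(set$ratio_km_vmax, rep(0.025, 4), tolerance = 1e-8)
})

test_that("double-reciprocal lines come from the iterative fit", {
  fit <- fit_michaelis_menten(mm_series(km = 5, vmax = 100))
  lb <- lineweaver_burk(fit)
  expect_equal(lb$lines$slope, 0.05, tolerance = 1e-7)     # Km/Vmax
  expect_equal(lb$lines$intercept, 0.01, tolerance = 1e-7) # 1/Vmax
  # two series with equal Km/Vmax but different Vmax give parallel lines
  fit2 <- fit_michaelis_menten(mm_series(km = 2.5, vmax = 50, internal = 250))
  lb2 <- lineweaver_burk(fit2)
  expect_equal(lb2$lines$slope, lb$lines$slope, tolerance = 1e-7)
  expect_false(isTRUE(all.equal(lb2$lines$intercept, lb$lines$intercept)))
  # non-positive rates are excluded from the transformed points
  rates_bad <- mm_series(5, 100) |>
    dplyr::mutate(rate_nmol_mg_min = replace(rate_nmol_mg_min, 1, 0))
  fitb <- fit_michaelis_menten(rates_bad[-1, ])
  fitb$data <- rates_bad
  expect_message(lbb <- lineweaver_burk(fitb), "non-positive")
  expect_identical(nrow(lbb$points), 7L)
})
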