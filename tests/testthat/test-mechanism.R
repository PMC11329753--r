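kmvmax_row <- function(internal, km, km_se = 0, vmax, vmax_se = 0, cov = 0) {
  tibble::tibble(internal_conc_uM = internal, km_uM = km, km_se = km_se,
                 vmax = vmax, vmax_se = vmax_se, cov_km_vmax = cov)
}

test_that("Km/Vmax ratios propagate uncertainty by the delta method", {
  set <- kmvmax_row(100, km = 5, vmax = 100)
  r <- km_vmax_ratios(set)
  expect_equal(r$ratio, 0.05)
  expect_equal(r$ratio_se, 0)
  # relative errors add in quadrature (zero covariance)
  set2 <- kmvmax_row(100, km = 5, km_se = 0.5, vmax = 100, vmax_se = 5)
  expect_equal(km_vmax_ratios(set2)$ratio_se, 0.05 * sqrt(0.01 + 0.0025),
               tolerance = 1e-9)
  # homogeneity: doubling Km and Vmax leaves the ratio unchanged
  set3 <- kmvmax_row(100, km = 10, km_se = 1, vmax = 200, vmax_se = 10)
  expect_equal(km_vmax_ratios(set3)$ratio, 0.05)
  expect_error(km_vmax_ratios(kmvmax_row(100, km = 5, vmax = -1)), "Vmax")
})

test_that("identical ratios give a null homogeneity statistic", {
  set <- dplyr::bind_rows(purrr::map(c(100, 250, 500, 1000), function(b) {
    kmvmax_row(b, km = 5, km_se = 0.2 * 2, vmax = 200, vmax_se = 0)
  }))
  # all ratios 0.025 with se 0.002
  test <- ratio_constancy_test(set)
  expect_equal(test$statistic, 0)
  expect_equal(test$p_value, 1)
  expect_identical(test$call, "ping_pong")
})

test_that("sequential-law apparent ratios are rejected as non-constant", {
  p <- rate_law_params(vmax = 200, km_ext = 5, km_int = 200, ki_ext = 5)
  app <- apparent_parameters(p, "sequential", c(100, 250, 500, 1000))
  expect_equal(app$ratio_km_vmax, c(0.075, 0.045, 0.035, 0.030))
  set <- tibble::tibble(
    internal_conc_uM = app$internal_conc_uM,
    km_uM = app$km_app_uM,
    km_se = 0.005 * app$vmax_app,  # gives se(ratio) = 0.005
    vmax = app$vmax_app, vmax_se = 0, cov_km_vmax = 0
  )
  test <- ratio_constancy_test(set, alpha = 0.05)
  expect_lt(test$p_value, 0.05)
  expect_identical(test$call, "sequential")
})

test_that("degenerate ratio sets are rejected as input", {
  expect_error(ratio_constancy_test(kmvmax_row(100, 5, vmax = 100)), "df")
  discordant <- dplyr::bind_rows(kmvmax_row(100, 5, vmax = 100),
                                 kmvmax_row(250, 6, vmax = 100))
  expect_error(ratio_constancy_test(discordant), "replicate-based")
})

test_that("the nested global fit separates the two laws", {
  p_seq <- rate_law_params(vmax = 200, km_ext = 5, km_int = 200, ki_ext = 5)
  p_pp <- rate_law_params(vmax = 200, km_ext = 5, km_int = 200)
  grid <- tidyr::expand_grid(internal_conc_uM = c(100, 250, 500, 1000),
                             external_conc_uM = assay_external)
  # noiseless ping-pong truth: no support for the extra parameter
  tab_pp <- dplyr::mutate(grid, rate_nmol_mg_min = exchange_flux(
    p_pp, "ping_pong", external_conc_uM, internal_conc_uM))
  res_pp <- global_mechanism_fit(tab_pp)
  expect_identical(res_pp$call, "ping_pong")
  expect_lt(res_pp$statistic, 1e-6)
  # noiseless sequential truth: ki recovered, sequential called
  tab_seq <- dplyr::mutate(grid, rate_nmol_mg_min = exchange_flux(
    p_seq, "sequential", external_conc_uM, internal_conc_uM))
  res_seq <- global_mechanism_fit(tab_seq)
  expect_identical(res_seq$call, "sequential")
  expect_equal(unname(res_seq$fits$sequential[["ki_ext"]]), 5,
               tolerance = 1e-3)
  # a 5 % noisy realization still discriminates
  set.seed(101)
  tab_noisy <- dplyr::mutate(
    tab_seq,
    rate_sd = 0.05 * rate_nmol_mg_min,
    rate_nmol_mg_min = rate_nmol_mg_min * (1 + rnorm(dplyr::n(), sd = 0.05)))
  expect_identical(global_mechanism_fit(tab_noisy)$call, "sequential")
  # singular design: one internal concentration
  expect_error(global_mechanism_fit(dplyr::filter(tab_pp, internal_conc_uM == 100)),
               "Singular|internal")
})

test_that("both p-values are invariant to unit rescaling", {
  cfg <- sim_config(seed = 19)
  rates <- initial_rates_table(simulate_experiment_grid(cfg))
  set <- fit_mm_curves(rates)
  v1 <- classify_mechanism(set, rates)

  rates_scaled <- dplyr::mutate(rates,
                                rate_nmol_mg_min = 1000 * rate_nmol_mg_min,
                                rate_sd = 1000 * rate_sd)
  set_scaled <- fit_mm_curves(rates_scaled)
  v2 <- classify_mechanism(set_scaled, rates_scaled)
  expect_equal(v2$ratio_test$p_value, v1$ratio_test$p_value, tolerance = 1e-6)
  expect_equal(v2$global_fit$p_value, v1$global_fit$p_value, tolerance = 1e-4)

  rates_conc <- dplyr::mutate(rates,
                              external_conc_uM = external_conc_uM / 1000,
                              internal_conc_uM = internal_conc_uM / 1000)
  set_conc <- fit_mm_curves(rates_conc)
  v3 <- classify_mechanism(set_conc, rates_conc)
  expect_equal(v3$ratio_test$p_value, v1$ratio_test$p_value, tolerance = 1e-6)
  expect_equal(v3$global_fit$p_value, v1$global_fit$p_value, tolerance = 1e-4)
})

test_that("the combined verdict requires concordant tests", {
  cfg <- sim_config(seed = 23)
  rates <- initial_rates_table(simulate_experiment_grid(cfg))
  set <- fit_mm_curves(rates)
  v <- classify_mechanism(set, rates)
  expect_identical(v$call, "ping_pong")
  expect_identical(v$ratio_test$call, "ping_pong")
  expect_identical(v$global_fit$call, "ping_pong")
  td <- tidy(v)
  expect_identical(td$test, c("ratio_constancy", "global_fit"))
  expect_true(all(td$p.value >= 0 & td$p.value <= 1))

  # force discordance by replacing the ratio test's input with a sequential set
  p_seq <- rate_law_params(200, 5, 200, ki_ext = 10)
  app <- apparent_parameters(p_seq, "sequential", c(100, 250, 500, 1000))
  seq_set <- tibble::tibble(internal_conc_uM = app$internal_conc_uM,
                            km_uM = app$km_app_uM, km_se = 0.001 * app$km_app_uM,
                            vmax = app$vmax_app, vmax_se = 0, cov_km_vmax = 0)
  v_disc <- classify_mechanism(seq_set, rates)
  expect_identical(v_disc$ratio_test$call, "sequential")
  expect_identical(v_disc$global_fit$call, "ping_pong")
  expect_identical(v_disc$call, "inconclusive")
})
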