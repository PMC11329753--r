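test_that("background subtraction is point-wise on the replicate mean", {
  curve <- tibble::tibble(time_s = c(0, 10, 20), quantity_nmol_per_mg = c(1, 2, 3),
                          is_background = FALSE)
  bg <- tibble::tibble(time_s = c(0, 10, 20), quantity_nmol_per_mg = c(0.5, 0.5, 0.5))
  expect_equal(subtract_background(curve, bg)$quantity_nmol_per_mg,
               c(0.5, 1.5, 2.5))
  # curve minus itself is zero; zero background is the identity
  expect_equal(subtract_background(curve, curve)$quantity_nmol_per_mg,
               c(0, 0, 0))
  zero_bg <- dplyr::mutate(bg, quantity_nmol_per_mg = 0)
  expect_equal(subtract_background(curve, zero_bg)$quantity_nmol_per_mg,
               c(1, 2, 3))
  # replicate mean: two background replicates averaging to 0.5
  bg2 <- tibble::tibble(time_s = rep(c(0, 10, 20), 2),
                        quantity_nmol_per_mg = c(0.4, 0.4, 0.4, 0.6, 0.6, 0.6))
  expect_equal(subtract_background(curve, bg2)$quantity_nmol_per_mg,
               c(0.5, 1.5, 2.5))
  # non-interpolatable grids error
  bad_bg <- tibble::tibble(time_s = c(5, 10), quantity_nmol_per_mg = c(0, 0))
  expect_error(subtract_background(curve, bad_bg), "interpolat")
})

test_that("noiseless exchange curves are recovered to numerical precision", {
  d <- exact_exchange_curve(beta = 10, k = 3, d = 2)
  fit <- fit_exchange_curve(d)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimate), c(10, 3, 2), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # model limits: Q(d) = 0 and Q -> beta
  expect_equal(uptake_model(2, 10, 3, 2), 0)
  expect_equal(uptake_model(1e7, 10, 3, 2), 10, tolerance = 1e-9)
  # fixing the delay constrains d and still recovers (beta, k)
  fit_fixed <- fit_exchange_curve(d, fix_delay = 2)
  expect_equal(unname(fit_fixed$estimate), c(10, 3, 2), tolerance = 1e-8)
  expect_identical(unname(fit_fixed$se["d"]), 0)
})

test_that("the fit matches an exhaustive lattice search", {
  d <- exact_exchange_curve(beta = 10, k = 3, d = 2)
  fit <- fit_exchange_curve(d)
  lattice <- grid_search_exchange(
    d$time_s, d$quantity_nmol_per_mg,
    beta_grid = seq(10 * 0.995, 10 * 1.005, length.out = 200),
    k_grid = seq(3 * 0.995, 3 * 1.005, length.out = 200),
    d_grid = seq(2 * 0.995, 2 * 1.005, length.out = 200)
  )
  expect_lt(abs(fit$estimate[["k"]] - lattice$k) / lattice$k, 1e-4)
  expect_lt(abs(fit$estimate[["beta"]] - lattice$beta) / lattice$beta, 1e-4)
})

test_that("refitting the fitted curve is a fixed point and scaling is equivariant", {
  d <- exact_exchange_curve(beta = 8, k = 2.5, d = 1)
  fit <- fit_exchange_curve(d)
  refit <- fit_exchange_curve(
    tibble::tibble(time_s = d$time_s, quantity_nmol_per_mg = predict(fit)))
  expect_equal(refit$estimate, fit$estimate, tolerance = 1e-8)

  scaled <- dplyr::mutate(d, quantity_nmol_per_mg = 3.7 * quantity_nmol_per_mg)
  fit_s <- fit_exchange_curve(scaled)
  expect_equal(fit_s$estimate[["beta"]], 3.7 * fit$estimate[["beta"]],
               tolerance = 1e-6)
  expect_equal(fit_s$estimate[["k"]], 3.7 * fit$estimate[["k"]],
               tolerance = 1e-6)
  expect_equal(fit_s$estimate[["d"]], fit$estimate[["d"]], tolerance = 1e-4)
})

test_that("degenerate curves are flagged, not silently fitted", {
  flat <- tibble::tibble(time_s = assay_times,
                         quantity_nmol_per_mg = rep(0, length(assay_times)))
  fit <- fit_exchange_curve(flat)
  expect_false(fit$converged)
  expect_identical(fit$flag, "no_transport")
  expect_identical(unname(fit$se["k"]), Inf)
  expect_error(fit_exchange_curve(exact_exchange_curve(10, 3, 0, times = c(0, 10, 20))),
               "4 distinct")
})

test_that("tidy and glance expose the exchange-fit results", {
  fit <- fit_exchange_curve(exact_exchange_curve(10, 3, 2))
  td <- tidy(fit)
  expect_identical(td$term, c("beta", "k", "d"))
  expect_equal(td$estimate, c(10, 3, 2), tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_identical(gl$flag, "ok")
})

test_that("initial-rate aggregation follows replicate mean and SD", {
  ks <- c(60, 66, 72)
  plate <- purrr::imap(ks, function(k, i) {
    dplyr::mutate(exact_exchange_curve(beta = 150, k = k),
                  internal_conc_uM = 1000, external_conc_uM = 2.5,
                  replicate = sprintf("t%d", i), is_background = FALSE)
  }) |> dplyr::bind_rows()
  tab <- initial_rates_table(plate)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$rate_nmol_mg_min, 66, tolerance = 1e-6)
  expect_equal(tab$rate_sd, 6, tolerance = 1e-5)
  expect_identical(tab$n_replicates, 3L)

  # identical replicates: SD exactly 0
  plate_same <- dplyr::mutate(plate, quantity_nmol_per_mg =
                                uptake_model(time_s, 150, 66))
  tab_same <- initial_rates_table(plate_same)
  expect_equal(tab_same$rate_nmol_mg_min, 66, tolerance = 1e-6)
  expect_equal(tab_same$rate_sd, 0, tolerance = 1e-8)
})

test_that("noise-free grid rates reproduce the generating rate law", {
  cfg <- quiet_cfg(seed = 3, internal_conc_uM = c(250, 1000),
                   external_conc_uM = c(1, 2.5, 10, 20),
                   technical_replicates = 1, biological_replicates = 1)
  plate <- simulate_experiment_grid(cfg)
  tab <- initial_rates_table(plate)
  truth <- exchange_flux(cfg$params, cfg$mechanism,
                         a_ext = tab$external_conc_uM,
                         b_int = tab$internal_conc_uM)
  expect_equal(tab$rate_nmol_mg_min, truth, tolerance = 1e-6)
})

test_that("single-replicate conditions fall back to the fit standard error", {
  cfg <- sim_config(seed = 5, internal_conc_uM = 1000, external_conc_uM = 2.5,
                    technical_replicates = 1, biological_replicates = 1,
                    background_external_uM = NULL,
                    noise = noise_model(counting_cv = 0.05, background_offset = 0,
                                        biological_cv = 0))
  tab <- initial_rates_table(simulate_experiment_grid(cfg))
  expect_identical(tab$n_replicates, 1L)
  expect_true(is.finite(tab$rate_sd) && tab$rate_sd > 0)
})
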