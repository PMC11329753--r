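test_that("infinite external pool reduces the two-pool curve to the exchange equation", {
  deviation_at_volume <- function(vol) {
    cfg <- quiet_cfg(seed = 1, geometry = list(external_volume = vol))
    prep <- liposome_prep(internal_conc = 1000, external_conc = 2.5,
                          external_volume = vol)
    curve <- simulate_uptake_curve(cfg, prep)
    flux <- exchange_flux(cfg$params, "ping_pong", 2.5, 1000)
    beta <- 1000 * prep$internal_volume_per_mg * prep$protein_per_well / 1000 /
      prep$protein_per_well
    ref <- uptake_model(curve$time_s, beta, flux)
    keep <- curve$time_s > 0
    max(abs(curve$quantity_nmol_per_mg[keep] - ref[keep]) / ref[keep])
  }
  expect_lt(deviation_at_volume(1e12), 1e-8)
  # deviation shrinks monotonically as the external pool grows
  devs <- vapply(c(1e3, 1e5, 1e7, 1e9), deviation_at_volume, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("finite pools equilibrate at the label-partition plateau", {
  # N_in = 1 nmol, N_out = 4 nmol, fully labelled outside
  cfg <- quiet_cfg(seed = 1, time_points_s = c(0, 60, 600, 6000, 60000))
  prep <- liposome_prep(internal_conc = 1000, external_conc = 20,
                        internal_volume_per_mg = 1000,
                        protein_per_well = 0.001, external_volume = 200)
  curve <- simulate_uptake_curve(cfg, prep)
  l_in <- curve$quantity_nmol_per_mg * prep$protein_per_well
  expect_equal(dplyr::last(l_in), 4 * 1 / (1 + 4), tolerance = 1e-9)
  # monotone accumulation, bounded by min(N_in, L_tot)/protein
  q <- curve$quantity_nmol_per_mg
  expect_true(all(diff(q) >= 0))
  expect_true(all(q <= min(1, 4) / prep$protein_per_well + 1e-12))
})

test_that("substrate-free liposomes give a flat background trace", {
  cfg <- sim_config(noise = noise_model(counting_cv = 0, background_offset = 0.5,
                                        poisson_scale = 0, biological_cv = 0),
                    seed = 1)
  prep <- liposome_prep(internal_conc = 0, external_conc = 2.5)
  curve <- simulate_uptake_curve(cfg, prep)
  expect_true(all(curve$quantity_nmol_per_mg == 0.5))
  expect_true(all(curve$is_background))
})

test_that("an empty external pool with nonzero specific activity is a configuration error", {
  cfg <- quiet_cfg(seed = 1)
  prep <- liposome_prep(internal_conc = 1000, external_conc = 0)
  expect_error(simulate_uptake_curve(cfg, prep), "N_out")
})

test_that("the experiment grid has the designed layout and honours the seed", {
  cfg <- quiet_cfg(seed = 7, technical_replicates = 3, biological_replicates = 1)
  plate <- simulate_experiment_grid(cfg)
  curves <- dplyr::distinct(plate, condition_id, replicate)
  expect_identical(nrow(curves), 99L)  # 4 x 8 x 3 + 3 background
  expect_identical(nrow(plate), 99L * 9L)
  expect_identical(sum(plate$is_background), 3L * 9L)

  # bit-reproducible under a fixed seed
  cfg2 <- sim_config(seed = 11)
  expect_identical(simulate_experiment_grid(cfg2), simulate_experiment_grid(cfg2))

  # noise-free replicates are identical
  wide <- tidyr::pivot_wider(plate, names_from = replicate,
                             values_from = quantity_nmol_per_mg)
  expect_equal(wide$b1.t1, wide$b1.t2)
  expect_equal(wide$b1.t1, wide$b1.t3)

  # grid quantities round-trip through the plate CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(plate, path)
  expect_equal(as.data.frame(read_plate_csv(path)), as.data.frame(plate),
               tolerance = 1e-12)
})

test_that("two-state melt curves have the constructed midpoint", {
  melt <- simulate_melt_curve(tm = 51, baselines = c(0, 0, 1, 0))
  i <- which.min(abs(melt$temperature_C - 51))
  expect_equal(melt$ratio[i], 0.5, tolerance = 1e-9)  # theta(Tm) = 1/2
  melt2 <- simulate_melt_curve(tm = 51)
  expect_equal(melt2$ratio[i], (0.8 + 1.0) / 2, tolerance = 1e-9)
  expect_error(simulate_melt_curve(tm = 51, vanthoff_dH = -5), "vanthoff_dH")
})

test_that("chromatogram synthesis places peaks where asked", {
  one <- simulate_chromatogram(
    tibble::tibble(volume_mL = 12, height = 1, width_mL = 0.3))
  expect_equal(one$volume_mL[which.max(one$absorbance)], 12)
  none <- simulate_chromatogram(tibble::tibble(volume_mL = numeric(),
                                               height = numeric(),
                                               width_mL = numeric()))
  expect_true(all(none$absorbance == 0))
  two <- simulate_chromatogram(
    tibble::tibble(volume_mL = c(10, 14), height = c(1, 0.6),
                   width_mL = c(0.3, 0.3)))
  expect_equal(peak_elution_volume(two, window = c(8, 12)), 10)
  expect_equal(peak_elution_volume(two, window = c(12, 16)), 14)
})
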