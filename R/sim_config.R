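#' Measurement-noise model for simulated uptake data
#'
#' Emulates the error structure of filter-plate scintillation counting:
#' a multiplicative Gaussian error on every measured quantity, an additive
#' nonspecific background signal, an optional Poisson counting layer, and a
#' between-batch (biological-replicate) lognormal multiplier on the maximal
#' rate.
#'
#' @param counting_cv Coefficient of variation of the multiplicative Gaussian
#'   error applied to each measured quantity (default 0.05).
#' @param background_offset Additive nonspecific signal, nmol/mg equivalent
#'   (default 0.5). Background-control liposomes read at this level.
#' @param poisson_scale Counts per nmol/mg for the Poisson counting layer;
#'   0 (default) disables it.
#' @param biological_cv Coefficient of variation of the lognormal Vmax
#'   multiplier applied per biological replicate batch (default 0.10).
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(counting_cv = 0.05, background_offset = 0.5,
                        poisson_scale = 0, biological_cv = 0.10) {
  assert_scalar_num(counting_cv, "counting_cv", lower = 0)
  assert_scalar_num(background_offset, "background_offset", lower = 0)
  assert_scalar_num(poisson_scale, "poisson_scale", lower = 0)
  assert_scalar_num(biological_cv, "biological_cv", lower = 0)
  structure(
    list(counting_cv = counting_cv, background_offset = background_offset,
         poisson_scale = poisson_scale, biological_cv = biological_cv),
    class = "noise_model"
  )
}

#' Proteoliposome preparation geometry for one transport condition
#'
#' Describes one well of a filter-plate uptake assay: the loaded internal
#' substrate, the external radiolabelled substrate, and the pool geometry that
#' converts concentrations into absolute substrate amounts. The entrapped
#' internal volume per mg protein and the counting efficiency are not
#' measurable from published information; their defaults are explicit,
#' configurable placeholders chosen to give realistic curve scales.
#'
#' @param internal_conc Internal substrate concentration, uM (>= 0; 0 gives a
#'   background-control liposome).
#' @param external_conc External labelled substrate concentration, uM.
#' @param internal_volume_per_mg Entrapped liposome volume, uL per mg protein
#'   (default 200).
#' @param protein_per_well Carrier protein per well, mg (default 0.001).
#' @param external_volume External assay volume, uL (default 200).
#' @param external_specific_activity Fraction of external substrate carrying
#'   the label, in `[0, 1]` (default 1).
#'
#' @return An object of class `liposome_prep`.
#' @export
liposome_prep <- function(internal_conc, external_conc,
                          internal_volume_per_mg = 200,
                          protein_per_well = 0.001,
                          external_volume = 200,
                          external_specific_activity = 1) {
  assert_scalar_num(internal_conc, "internal_conc", lower = 0)
  assert_scalar_num(external_conc, "external_conc", lower = 0)
  assert_scalar_num(internal_volume_per_mg, "internal_volume_per_mg")
  assert_scalar_num(protein_per_well, "protein_per_well")
  assert_scalar_num(external_volume, "external_volume")
  assert_scalar_num(external_specific_activity, "external_specific_activity",
                    lower = 0, upper = 1)
  if (internal_volume_per_mg <= 0 || protein_per_well <= 0 ||
      external_volume <= 0) {
    stop_input("All volumes and the protein amount must be > 0.")
  }
  structure(
    list(internal_conc = internal_conc, external_conc = external_conc,
         internal_volume_per_mg = internal_volume_per_mg,
         protein_per_well = protein_per_well,
         external_volume = external_volume,
         external_specific_activity = external_specific_activity),
    class = "liposome_prep"
  )
}

#' Full generative description of a two-substrate transport experiment
#'
#' Collects everything needed to simulate a plate of homo-exchange uptake
#' curves: mechanism and rate law, the internal x external concentration
#' design grid, sampling times, replication, pool geometry, noise model, and
#' the seed. The defaults mirror a typical oxoglutarate-carrier experiment:
#' four internal loads (0.10-1.00 mM), an external series of 0.5-20 uM,
#' sampling at 0-120 s, three technical times two biological replicates, and
#' background (substrate-free) control liposomes.
#'
#' @param mechanism `"ping_pong"` or `"sequential"`.
#' @param params A [rate_law_params()] object.
#' @param internal_conc_uM Internal substrate concentrations, uM (non-zero
#'   loads; background controls are generated separately).
#' @param external_conc_uM External labelled substrate concentrations, uM.
#' @param time_points_s Sampling times, seconds; non-negative, strictly
#'   increasing.
#' @param filtration_delay_s Filtration dead time d, seconds (default 0;
#'   typical instrument values are 0-5 s). The simulated quantity is clamped
#'   at 0 for t < d.
#' @param technical_replicates,biological_replicates Replication counts
#'   (defaults 3 and 2). Each biological replicate is a batch with its own
#'   Vmax multiplier (see [noise_model()]).
#' @param background_external_uM External concentration at which the
#'   substrate-free background control is recorded (default 2.5 uM); `NULL`
#'   omits background curves.
#' @param noise A [noise_model()].
#' @param geometry Named list of pool-geometry defaults passed to
#'   [liposome_prep()] (fields `internal_volume_per_mg`, `protein_per_well`,
#'   `external_volume`, `external_specific_activity`).
#' @param seed Integer seed; fixing it makes simulated output bit-reproducible.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_experiment_grid()], [simulate_uptake_curve()]
#' @export
sim_config <- function(mechanism = "ping_pong",
                       params = rate_law_params(vmax = 200, km_ext = 5,
                                                km_int = 200),
                       internal_conc_uM = c(100, 250, 500, 1000),
                       external_conc_uM = c(0.5, 1, 1.5, 2.5, 5, 10, 15, 20),
                       time_points_s = c(0, 10, 20, 30, 40, 50, 60, 90, 120),
                       filtration_delay_s = 0,
                       technical_replicates = 3,
                       biological_replicates = 2,
                       background_external_uM = 2.5,
                       noise = noise_model(),
                       geometry = list(),
                       seed = NULL) {
  mechanism <- match_mechanism(mechanism)
  if (!inherits(params, "rate_law_params")) {
    stop_input("`params` must be created with rate_law_params().")
  }
  if (!length(internal_conc_uM) || !length(external_conc_uM)) {
    stop_input("Concentration grids must be non-empty.")
  }
  if (any(internal_conc_uM <= 0) || any(external_conc_uM <= 0)) {
    stop_input("Grid concentrations must be > 0 (background is configured via `background_external_uM`).")
  }
  if (!is.numeric(time_points_s) || length(time_points_s) < 2L ||
      any(time_points_s < 0) || any(diff(time_points_s) <= 0)) {
    stop_input("`time_points_s` must be non-negative and strictly increasing.")
  }
  assert_scalar_num(filtration_delay_s, "filtration_delay_s", lower = 0)
  assert_scalar_num(technical_replicates, "technical_replicates", lower = 1)
  assert_scalar_num(biological_replicates, "biological_replicates", lower = 1)
  assert_scalar_num(background_external_uM, "background_external_uM",
                    allow_null = TRUE)
  if (!inherits(noise, "noise_model")) {
    stop_input("`noise` must be created with noise_model().")
  }
  if (!is.null(seed)) assert_scalar_num(seed, "seed")
  geom_defaults <- list(internal_volume_per_mg = 200, protein_per_well = 0.001,
                        external_volume = 200, external_specific_activity = 1)
  unknown <- setdiff(names(geometry), names(geom_defaults))
  if (length(unknown)) {
    stop_input("Unknown geometry field(s): %s.", paste(unknown, collapse = ", "))
  }
  geometry <- modifyList(geom_defaults, geometry)
  structure(
    list(mechanism = mechanism, params = params,
         internal_conc_uM = sort(unique(internal_conc_uM)),
         external_conc_uM = sort(unique(external_conc_uM)),
         time_points_s = time_points_s,
         filtration_delay_s = filtration_delay_s,
         technical_replicates = as.integer(technical_replicates),
         biological_replicates = as.integer(biological_replicates),
         background_external_uM = background_external_uM,
         noise = noise, geometry = geometry,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  mechanism : %s\n", x$mechanism))
  cat(sprintf("  internal  : %s uM\n", paste(x$internal_conc_uM, collapse = ", ")))
  cat(sprintf("  external  : %s uM\n", paste(x$external_conc_uM, collapse = ", ")))
  cat(sprintf("  times     : %s s\n", paste(x$time_points_s, collapse = ", ")))
  cat(sprintf("  replicates: %d technical x %d biological\n",
              x$technical_replicates, x$biological_replicates))
  cat(sprintf("  noise     : cv %.3g, background %.3g nmol/mg, biological cv %.3g\n",
              x$noise$counting_cv, x$noise$background_offset,
              x$noise$biological_cv))
  cat(sprintf("  seed      : %s\n", x$seed %||% "unset"))
  invisible(x)
}
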