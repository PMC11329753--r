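#' Validate plate-format uptake data
#'
#' Checks a plate CSV (or tibble) for schema and consistency problems
#' without mutating the data: required columns, finite non-negative
#' quantities where expected, monotone time grids per curve, replicate
#' completeness, and the presence of background controls.
#'
#' @param x A file path or a plate-format tibble.
#'
#' @return A tibble of findings with columns `level` (`"error"`,
#'   `"warning"`), `check`, `message`; zero rows means no problems.
#' @export
validate_input <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop_input("File not found: %s", x)
    x <- read_plate_csv(x)
  }
  findings <- list()
  note <- function(level, check, message) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      level = level, check = check, message = message)
  }
  missing <- setdiff(plate_columns(), names(x))
  if (length(missing)) {
    note("error", "columns",
         paste("Missing column(s):", paste(missing, collapse = ", ")))
    return(dplyr::bind_rows(findings))
  }
  if (any(!is.finite(x$quantity_nmol_per_mg))) {
    note("error", "quantities", "Non-finite quantities present.")
  }
  if (any(x$internal_conc_uM < 0) || any(x$external_conc_uM < 0)) {
    note("error", "concentrations", "Negative concentrations present.")
  }
  curves <- split(x, interaction(x$condition_id, x$replicate, drop = TRUE))
  bad_time <- purrr::map_lgl(curves, ~ any(diff(.x$time_s) <= 0))
  if (any(bad_time)) {
    note("error", "times",
         sprintf("Non-monotone times in %d curve(s), e.g. %s.",
                 sum(bad_time), names(curves)[which(bad_time)[1]]))
  }
  n_points <- purrr::map_int(curves, nrow)
  if (length(unique(n_points)) > 1L) {
    note("warning", "replicates",
         "Curves have unequal numbers of time points; replicate set may be incomplete.")
  }
  if (!any(x$is_background)) {
    note("warning", "background",
         "No background-control rows; analysis proceeds without subtraction.")
  }
  flagged <- x$internal_conc_uM == 0 & !x$is_background
  if (any(flagged)) {
    note("warning", "background",
         "Rows with internal 0 uM are not flagged as background.")
  }
  dplyr::bind_rows(findings)
}

config_to_sim <- function(config) {
  sim <- config$simulate
  p <- sim$params %||% list()
  sim_config(
    mechanism = sim$mechanism %||% "ping_pong",
    params = rate_law_params(
      vmax = p$vmax %||% 200, km_ext = p$km_ext %||% 5,
      km_int = p$km_int %||% 200, ki_ext = p$ki_ext %||% 0
    ),
    internal_conc_uM = unlist(sim$internal_conc_uM) %||% c(100, 250, 500, 1000),
    external_conc_uM = unlist(sim$external_conc_uM) %||%
      c(0.5, 1, 1.5, 2.5, 5, 10, 15, 20),
    time_points_s = unlist(sim$time_points_s) %||%
      c(0, 10, 20, 30, 40, 50, 60, 90, 120),
    filtration_delay_s = sim$filtration_delay_s %||% 0,
    technical_replicates = sim$replicates$technical %||% 3,
    biological_replicates = sim$replicates$biological %||% 2,
    background_external_uM = sim$background_external_uM %||% 2.5,
    noise = do.call(noise_model, sim$noise %||% list()),
    geometry = sim$geometry %||% list(),
    seed = config$seed
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_input("Config file not found: %s", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop_input("`config` must be a list or a YAML/JSON path.")
  has_sim <- !is.null(config$simulate)
  has_data <- !is.null(config$data)
  if (!has_sim && !has_data) {
    stop_input("Config must provide either a `simulate` block or a `data` path.")
  }
  if (has_data && !file.exists(config$data)) {
    stop_input("Config `data` file not found: %s", config$data)
  }
  for (f in c("melt_traces", "sec")) {
    paths <- switch(f,
      melt_traces = purrr::map_chr(config$tm$traces %||% list(), "path"),
      sec = unlist(config$sec[c("trace", "standards")])
    )
    paths <- as.character(paths %||% character(0))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop_input("Referenced file(s) not found: %s", paste(missing, collapse = ", "))
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end: simulate (or ingest and validate) a
#' plate of uptake curves, subtract background, estimate initial rates, fit
#' Michaelis-Menten curves per internal concentration, classify the kinetic
#' mechanism, and optionally extract melting temperatures and the SEC
#' oligomeric state. All outputs (plate, rates, and kinetics CSVs, verdict
#' JSON, diagnostic plots, run log) are written under `out_dir`. The verdict
#' JSON carries a provenance block (config hash, seed, package version) and
#' is byte-identical across runs with the same config; timestamps go to the
#' run log only.
#'
#' @param config Path to a YAML/JSON configuration or an equivalent named
#'   list. Top-level fields: `seed`; either `simulate` (fields mirroring
#'   [sim_config()]) or `data` (path to a plate CSV); optional `analysis`
#'   (`alpha`, `weighting`, `fix_delay`), `tm` (`traces`: list of
#'   `{label, path}`), `sec` (`trace`, `standards`, `v0`, `vt`,
#'   `protomer_mw`, `micelle_mass`, `window`).
#' @param out_dir Output directory; created if missing.
#'
#' @return An `analysis_report` list with elements `plate`, `rates`,
#'   `kinetics`, `verdict`, `tm`, `sec`, `provenance`, `paths`; returned
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character()
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_msg("stage '%s' failed: %s", name, conditionMessage(e))
      writeLines(log_lines, log_path)
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "carrierkin_pipeline_error", parent = e)
    })
  }

  provenance <- list(
    config_hash = rlang::hash(config),
    seed = config$seed %||% NA,
    package_version = as.character(packageVersion("carrierkin"))
  )
  alpha <- config$analysis$alpha %||% 0.05
  weighting <- config$analysis$weighting %||% "inverse_variance"

  plate <- stage("input", {
    if (!is.null(config$simulate)) {
      log_msg("simulating experiment grid (seed %s)", config$seed %||% "unset")
      simulate_experiment_grid(config_to_sim(config))
    } else {
      log_msg("reading plate data from %s", config$data)
      plate <- read_plate_csv(config$data)
      problems <- validate_input(plate)
      for (i in seq_len(nrow(problems))) {
        log_msg("validation %s [%s]: %s", problems$level[i],
                problems$check[i], problems$message[i])
      }
      if (any(problems$level == "error")) {
        stop_input("Input validation failed; see run log.")
      }
      plate
    }
  })
  write_plate_csv(plate, file.path(out_dir, "plate.csv"))

  rates <- stage("initial_rates", {
    log_msg("fitting %d uptake curves",
            nrow(dplyr::distinct(plate, .data$condition_id, .data$replicate)))
    initial_rates_table(plate, fix_delay = config$analysis$fix_delay)
  })
  write_rates_csv(rates, file.path(out_dir, "rates.csv"))

  kinetics <- stage("mm_kinetics", {
    fit_mm_curves(rates, weighting = weighting)
  })
  write_kinetics_csv(kinetics, file.path(out_dir, "kinetics.csv"))

  n_internal <- length(unique(kinetics$internal_conc_uM))
  if (n_internal < 2L) {
    log_msg("only one internal concentration: global fit skipped")
  }
  verdict <- stage("mechanism", {
    if (n_internal < 2L) {
      # ratio test is degenerate too (df = n - 1 = 0); surface that clearly
      ratio_constancy_test(kinetics, alpha = alpha)
    } else {
      classify_mechanism(kinetics, rates, alpha = alpha)
    }
  })
  write_verdict_json(verdict, file.path(out_dir, "verdict.json"),
                     provenance = provenance)
  log_msg("mechanism call: %s", verdict$call)

  tm_results <- NULL
  if (!is.null(config$tm)) {
    tm_results <- stage("thermostability", {
      fits <- purrr::map(config$tm$traces, function(tr) {
        res <- compute_tm(read_melt_csv(tr$path),
                          smoothing_window = config$tm$smoothing_window %||% 2)
        tibble::tibble(label = tr$label %||% tr$path, tm_C = res$tm,
                       quality = res$quality)
      }) |> dplyr::bind_rows()
      readr::write_csv(fits, file.path(out_dir, "tm.csv"))
      fits
    })
  }

  sec_result <- NULL
  if (!is.null(config$sec)) {
    sec_result <- stage("sec", {
      std <- read_standards_csv(config$sec$standards)
      cal <- fit_calibration(std, v0 = config$sec$v0 %||% 8,
                             vt = config$sec$vt %||% 24)
      chrom <- read_chromatogram_csv(config$sec$trace)
      ve <- peak_elution_volume(chrom, window = unlist(config$sec$window))
      res <- oligomeric_state(apparent_mw(cal, ve),
                              protomer_mw = config$sec$protomer_mw,
                              micelle_mass = config$sec$micelle_mass %||% 135)
      res$elution_volume_mL <- ve
      readr::write_csv(res, file.path(out_dir, "sec.csv"))
      res
    })
  }

  stage("plots", {
    pdf_path <- file.path(out_dir, "plots.pdf")
    grDevices::pdf(pdf_path, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    print(plot_michaelis_menten(kinetics))
    print(plot_lineweaver_burk(kinetics))
    print(plot_km_vmax(kinetics))
    invisible(pdf_path)
  })

  log_msg("pipeline complete")
  writeLines(log_lines, log_path)
  invisible(structure(
    list(plate = plate, rates = rates, kinetics = kinetics, verdict = verdict,
         tm = tm_results, sec = sec_result, provenance = provenance,
         paths = list(out_dir = out_dir)),
    class = "analysis_report"
  ))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  conditions: %d, rates: %d, internal concentrations: %d\n",
              nrow(x$rates), sum(!is.na(x$rates$rate_nmol_mg_min)),
              length(unique(x$kinetics$internal_conc_uM))))
  cat(sprintf("  mechanism call: %s\n", x$verdict$call))
  cat(sprintf("  outputs in: %s\n", x$paths$out_dir))
  invisible(x)
}
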