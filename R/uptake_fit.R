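#' Subtract the background-control signal from uptake curves
#'
#' Background controls (substrate-free liposomes) measure nonspecific label
#' retention. Their replicate-mean trace is subtracted point-wise from every
#' transport curve. If `background` is `NULL` the rows flagged
#' `is_background` within `data` are used. Time grids must match or be
#' interpolatable (background spanning the curve's time range). Input data
#' are never modified in place.
#'
#' @param data A plate-format tibble (see [write_plate_csv()]) or any tibble
#'   with `time_s`, `quantity_nmol_per_mg`, and (if `background` is `NULL`)
#'   `is_background`.
#' @param background Optional tibble of background measurements with
#'   `time_s`, `quantity_nmol_per_mg`.
#'
#' @return The background-subtracted tibble, with background rows removed.
#' @export
subtract_background <- function(data, background = NULL) {
  assert_cols(data, c("time_s", "quantity_nmol_per_mg"))
  if (is.null(background)) {
    assert_cols(data, "is_background")
    background <- dplyr::filter(data, .data$is_background)
    data <- dplyr::filter(data, !.data$is_background)
    if (!nrow(background)) {
      warn("No background rows found; returning data unchanged.")
      return(data)
    }
  } else {
    assert_cols(background, c("time_s", "quantity_nmol_per_mg"), "background")
    if ("is_background" %in% names(data)) {
      data <- dplyr::filter(data, !.data$is_background)
    }
  }
  bg_mean <- background |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(bg = mean(.data$quantity_nmol_per_mg), .groups = "drop")
  times <- sort(unique(data$time_s))
  if (all(times %in% bg_mean$time_s)) {
    bg_at <- bg_mean$bg[match(data$time_s, bg_mean$time_s)]
  } else {
    if (min(times) < min(bg_mean$time_s) || max(times) > max(bg_mean$time_s) ||
        nrow(bg_mean) < 2L) {
      stop_input("Background time grid does not cover the data and cannot be interpolated.")
    }
    bg_at <- approx(bg_mean$time_s, bg_mean$bg, xout = data$time_s)$y
  }
  dplyr::mutate(data, quantity_nmol_per_mg = .data$quantity_nmol_per_mg - bg_at)
}

exchange_residuals <- function(par, t, q, fix_delay = NULL) {
  beta <- par[["beta"]]; k <- par[["k"]]
  d <- if (is.null(fix_delay)) par[["d"]] else fix_delay
  uptake_model(t, beta, k, d) - q
}

exchange_jacobian <- function(par, t, q, fix_delay = NULL) {
  beta <- par[["beta"]]; k <- par[["k"]]
  d <- if (is.null(fix_delay)) par[["d"]] else fix_delay
  u <- (k / (60 * beta)) * (t - d)
  e <- exp(-u)
  j <- cbind(beta = (1 - e) - u * e, k = e * (t - d) / 60)
  if (is.null(fix_delay)) j <- cbind(j, d = -(k / 60) * e)
  j
}

#' Fit an uptake curve to the exponential exchange equation
#'
#' Estimates `(beta, k, d)` of [uptake_model()] by Levenberg-Marquardt
#' nonlinear least squares (unweighted, since per-point counting errors are
#' unknown for real data). All rows supplied are fitted jointly, so passing
#' several replicates pools them; the usual workflow fits replicates
#' separately via [initial_rates_table()]. Starting values are
#' `beta = max(Q)`, `k` from the slope of the first two rising points,
#' `d = 0`; box constraints `beta in (0, 10 max(Q)]`, `k > 0`,
#' `d in [-10, 30]` s keep the optimizer away from degenerate exponentials.
#'
#' @param data Tibble with columns `time_s` and `quantity_nmol_per_mg`
#'   (background-subtracted); at least 4 distinct time points.
#' @param fix_delay Optional fixed filtration delay, seconds. When supplied,
#'   `d` is held at this value and only `(beta, k)` are estimated.
#'
#' @return An object of class `exchange_fit` with elements `estimate`
#'   (named `beta`, `k`, `d`), `se`, `rss`, `converged`, `flag`
#'   (`"ok"`, `"no_transport"`, or `"non_convergence"`), `n`, `data`.
#'   Supports [tidy()], [glance()], [autoplot()], `predict()`.
#' @examples
#' d <- tibble::tibble(time_s = c(0, 10, 20, 30, 40, 50, 60, 90, 120),
#'                     quantity_nmol_per_mg = uptake_model(
#'                       c(0, 10, 20, 30, 40, 50, 60, 90, 120), 10, 3, 2))
#' tidy(fit_exchange_curve(d))
#' @export
fit_exchange_curve <- function(data, fix_delay = NULL) {
  assert_cols(data, c("time_s", "quantity_nmol_per_mg"))
  assert_scalar_num(fix_delay, "fix_delay", allow_null = TRUE)
  t <- data$time_s
  q <- data$quantity_nmol_per_mg
  ok <- is.finite(t) & is.finite(q)
  if (!all(ok)) stop_input("Times and quantities must be finite.")
  n_par <- if (is.null(fix_delay)) 3L else 2L
  if (length(unique(t)) < 4L || length(t) <= n_par) {
    stop_input("At least 4 distinct time points are required for the fit.")
  }

  new_fit <- function(est, se, rss, converged, flag) {
    structure(
      list(estimate = est, se = se, rss = rss, converged = converged,
           flag = flag, n = length(t), fix_delay = fix_delay, data = data),
      class = "exchange_fit"
    )
  }
  q_max <- max(q)
  if (diff(range(q)) < 1e-12 || q_max <= 0) {
    return(new_fit(c(beta = NA_real_, k = NA_real_, d = fix_delay %||% NA_real_),
                   c(beta = Inf, k = Inf, d = Inf), rss = sum((q - mean(q))^2),
                   converged = FALSE, flag = "no_transport"))
  }

  ord <- order(t)
  rising <- which(q[ord] > 0)
  k0 <- if (length(rising) >= 2L) {
    i1 <- ord[rising[1]]; i2 <- ord[rising[2]]
    s <- (q[i2] - q[i1]) / (t[i2] - t[i1]) * 60
    if (is.finite(s) && s > 0) s else q_max / 2
  } else {
    q_max / 2
  }
  par0 <- c(beta = q_max, k = k0)
  lower <- c(beta = q_max * 1e-6, k = q_max * 1e-9)
  upper <- c(beta = 10 * q_max, k = Inf)
  if (is.null(fix_delay)) {
    par0 <- c(par0, d = 0)
    lower <- c(lower, d = -10)
    upper <- c(upper, d = 30)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper,
      fn = exchange_residuals, jac = exchange_jacobian,
      t = t, q = q, fix_delay = fix_delay,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(new_fit(c(beta = NA_real_, k = NA_real_, d = fix_delay %||% NA_real_),
                   c(beta = Inf, k = Inf, d = Inf), rss = NA_real_,
                   converged = FALSE, flag = "non_convergence"))
  }
  est <- fit$par
  rss <- sum(fit$fvec^2)
  jac <- exchange_jacobian(est, t, q, fix_delay)
  se <- tryCatch({
    sigma2 <- rss / (length(t) - n_par)
    sqrt(pmax(diag(sigma2 * solve(crossprod(jac))), 0))
  }, error = function(e) rep(Inf, n_par))
  se <- setNames(se, colnames(jac))
  if (!is.null(fix_delay)) {
    est <- c(est, d = fix_delay)
    se <- c(se, d = 0)
  }
  new_fit(est[c("beta", "k", "d")], se[c("beta", "k", "d")], rss,
          converged = TRUE, flag = "ok")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("<exchange_fit>", x$flag, "\n")
  if (x$converged) {
    cat(sprintf("  beta = %.4g +/- %.3g nmol/mg\n", x$estimate["beta"], x$se["beta"]))
    cat(sprintf("  k    = %.4g +/- %.3g nmol mg^-1 min^-1\n", x$estimate["k"], x$se["k"]))
    cat(sprintf("  d    = %.4g +/- %.3g s%s\n", x$estimate["d"], x$se["d"],
                if (!is.null(x$fix_delay)) " (fixed)" else ""))
    cat(sprintf("  rss  = %.4g, n = %d\n", x$rss, x$n))
  }
  invisible(x)
}

#' @export
predict.exchange_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_s else newdata$time_s
  uptake_model(t, object$estimate["beta"], object$estimate["k"],
               object$estimate["d"])
}

#' Initial-rate table from a plate of uptake curves
#'
#' Fits every (internal, external, replicate) curve with
#' [fit_exchange_curve()] and aggregates the per-replicate initial rates `k`:
#' the condition rate is the replicate mean and its uncertainty the
#' replicate standard deviation (falling back to the fit standard error when
#' only one replicate exists). If background rows are present they are
#' subtracted first. Failed fits are carried as missing with a note, never
#' interpolated.
#'
#' @param data Plate-format tibble (see [write_plate_csv()]); the
#'   `condition_id` column is optional.
#' @param fix_delay Optional fixed filtration delay passed to the curve fits.
#' @param pool_replicates If `TRUE`, replicates of a condition are pooled
#'   into a single fit instead of being fitted separately (uncertainty is
#'   then the fit standard error of `k`). Default `FALSE`.
#'
#' @return A tibble with one row per condition: `internal_conc_uM`,
#'   `external_conc_uM`, `rate_nmol_mg_min`, `rate_sd`, `n_replicates`,
#'   `n_failed`, `converged`, `note`.
#' @export
initial_rates_table <- function(data, fix_delay = NULL, pool_replicates = FALSE) {
  assert_cols(data, c("internal_conc_uM", "external_conc_uM", "replicate",
                      "time_s", "quantity_nmol_per_mg"))
  if ("is_background" %in% names(data) && any(data$is_background)) {
    data <- subtract_background(data)
  }
  groups <- split(
    data,
    interaction(data$internal_conc_uM, data$external_conc_uM, drop = TRUE)
  )
  rows <- purrr::map(groups, function(g) {
    internal <- g$internal_conc_uM[1]
    external <- g$external_conc_uM[1]
    if (pool_replicates) {
      fit <- fit_exchange_curve(g, fix_delay = fix_delay)
      ok <- fit$converged
      return(tibble::tibble(
        internal_conc_uM = internal, external_conc_uM = external,
        rate_nmol_mg_min = if (ok) unname(fit$estimate["k"]) else NA_real_,
        rate_sd = if (ok) unname(fit$se["k"]) else NA_real_,
        n_replicates = length(unique(g$replicate)), n_failed = as.integer(!ok),
        converged = ok,
        note = if (ok) NA_character_ else paste("pooled fit:", fit$flag)
      ))
    }
    fits <- purrr::map(split(g, g$replicate), fit_exchange_curve,
                       fix_delay = fix_delay)
    ks <- purrr::map_dbl(fits, ~ unname(.x$estimate["k"]))
    ok <- purrr::map_lgl(fits, "converged")
    flags <- purrr::map_chr(fits, "flag")
    n_ok <- sum(ok)
    note <- if (all(ok)) NA_character_ else {
      paste0(sum(!ok), " replicate fit(s) failed: ",
             paste(unique(flags[!ok]), collapse = ", "))
    }
    tibble::tibble(
      internal_conc_uM = internal, external_conc_uM = external,
      rate_nmol_mg_min = if (n_ok) mean(ks[ok]) else NA_real_,
      rate_sd = if (n_ok > 1L) {
        sd(ks[ok])
      } else if (n_ok == 1L) {
        unname(fits[[which(ok)]]$se["k"])
      } else {
        NA_real_
      },
      n_replicates = length(fits), n_failed = sum(!ok),
      converged = n_ok > 0L, note = note
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$internal_conc_uM, .data$external_conc_uM)
}

#' Write an initial-rates table to CSV
#'
#' @param rates Tibble from [initial_rates_table()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rates_csv <- function(rates, path) {
  readr::write_csv(rates, path)
  invisible(path)
}
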