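as_kmvmax_df <- function(set) {
  assert_cols(set, c("internal_conc_uM", "km_uM", "vmax"), "set")
  if (any(duplicated(set$internal_conc_uM))) {
    stop_input("Internal concentrations in the Km/Vmax set must be distinct.")
  }
  if (any(!is.finite(set$km_uM)) || any(!is.finite(set$vmax))) {
    stop_input("Km/Vmax set contains non-finite estimates (failed fits?).")
  }
  if (any(set$vmax <= 0)) stop_input("Vmax must be > 0.")
  if (!"km_se" %in% names(set)) set$km_se <- 0
  if (!"vmax_se" %in% names(set)) set$vmax_se <- 0
  if (!"cov_km_vmax" %in% names(set)) set$cov_km_vmax <- 0
  set$cov_km_vmax[!is.finite(set$cov_km_vmax)] <- 0
  set
}

#' Km/Vmax ratios with delta-method standard errors
#'
#' Computes \eqn{r_i = K_{m,i}/V_{max,i}} for each internal concentration and
#' propagates the fit uncertainties by the delta method:
#' \deqn{se(r)^2 = r^2 [ (se_{Km}/K_m)^2 + (se_{Vmax}/V_{max})^2
#'   - 2 cov/(K_m V_{max}) ].}
#'
#' @param set A `kmvmax_set` from [fit_mm_curves()], or any data frame with
#'   columns `internal_conc_uM`, `km_uM`, `vmax` and optionally `km_se`,
#'   `vmax_se`, `cov_km_vmax`.
#'
#' @return A tibble with `internal_conc_uM`, `ratio` (min mg uM nmol^-1),
#'   `ratio_se`.
#' @export
km_vmax_ratios <- function(set) {
  set <- as_kmvmax_df(set)
  r <- set$km_uM / set$vmax
  var_r <- r^2 * ((set$km_se / set$km_uM)^2 + (set$vmax_se / set$vmax)^2 -
                    2 * set$cov_km_vmax / (set$km_uM * set$vmax))
  if (any(var_r < 0, na.rm = TRUE)) {
    warn("Delta-method variance was negative for some ratios; clamped to 0.")
    var_r <- pmax(var_r, 0)
  }
  tibble::tibble(internal_conc_uM = set$internal_conc_uM, ratio = r,
                 ratio_se = sqrt(var_r))
}

new_mechanism_test <- function(method, statistic, df, p_value, call, alpha,
                               ...) {
  structure(
    c(list(method = method, statistic = statistic, df = df,
           p_value = p_value, call = call, alpha = alpha), list(...)),
    class = "mechanism_test"
  )
}

#' @export
print.mechanism_test <- function(x, ...) {
  cat(sprintf("<mechanism_test: %s>\n", x$method))
  cat(sprintf("  statistic = %.4g on df %s, p = %.4g (alpha = %g)\n",
              x$statistic, paste(x$df, collapse = ", "), x$p_value, x$alpha))
  cat(sprintf("  supports: %s\n", x$call))
  invisible(x)
}

#' Ratio-constancy test for mechanism discrimination
#'
#' The ping-pong diagnostic: under a ping-pong mechanism the apparent
#' Km/Vmax ratio is the same at every internal (counter-substrate)
#' concentration, whereas under a sequential mechanism it decreases as the
#' internal concentration rises. The test compares the ratios to their
#' inverse-variance weighted mean with the homogeneity statistic
#' \eqn{X^2 = \sum_i ((r_i - \bar r)/se_i)^2}, referred to a chi-square
#' distribution with n - 1 degrees of freedom. `p >= alpha` supports
#' ping-pong; `p < alpha` supports a sequential mechanism.
#'
#' @inheritParams km_vmax_ratios
#' @param alpha Significance level (default 0.05).
#'
#' @return A `mechanism_test` with elements `statistic`, `df`, `p_value`,
#'   `call`, `ratios` (tibble from [km_vmax_ratios()]), `weighted_mean`.
#' @export
ratio_constancy_test <- function(set, alpha = 0.05) {
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1)
  ratios <- km_vmax_ratios(set)
  n <- nrow(ratios)
  if (n < 2L) {
    stop_input("At least 2 ratios are needed (df = n - 1 would be 0).")
  }
  if (any(ratios$ratio_se == 0)) {
    if (length(unique(ratios$ratio)) > 1L) {
      stop_input(paste("Zero standard errors with discordant ratios;",
                       "supply replicate-based SEs from the fits."))
    }
    x2 <- 0
  } else {
    w <- 1 / ratios$ratio_se^2
    rbar <- sum(w * ratios$ratio) / sum(w)
    x2 <- sum(((ratios$ratio - rbar) / ratios$ratio_se)^2)
  }
  rbar <- if (any(ratios$ratio_se == 0)) {
    mean(ratios$ratio)
  } else {
    sum(ratios$ratio / ratios$ratio_se^2) / sum(1 / ratios$ratio_se^2)
  }
  p <- pchisq(x2, df = n - 1L, lower.tail = FALSE)
  new_mechanism_test(
    method = "ratio_constancy", statistic = x2, df = n - 1L, p_value = p,
    call = if (p >= alpha) "ping_pong" else "sequential", alpha = alpha,
    ratios = ratios, weighted_mean = rbar
  )
}

rate_law_residuals <- function(par, a, b, v, w, sequential) {
  const <- if (sequential) par[["ki_ext"]] * par[["km_int"]] else 0
  pred <- par[["vmax"]] * a * b /
    (const + par[["km_int"]] * a + par[["km_ext"]] * b + a * b)
  sqrt(w) * (pred - v)
}

fit_rate_surface <- function(a, b, v, w, sequential, start) {
  lower <- setNames(rep(1e-9, length(start)), names(start))
  if (sequential) lower[["ki_ext"]] <- 0
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower,
      fn = rate_law_residuals, a = a, b = b, v = v, w = w,
      sequential = sequential,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !(fit$info %in% 1:4)) return(NULL)
  list(par = fit$par, rss = sum(fit$fvec^2))
}

#' Global nested rate-law comparison
#'
#' Fits the full rate surface v(A, B) with both the ping-pong law
#' (3 parameters) and the sequential law (4 parameters; the ping-pong law is
#' the nested `ki_ext = 0` case) by weighted least squares, and compares
#' them with the extra-sum-of-squares F test. A significant improvement by
#' the sequential law supports a sequential mechanism. This is a formal
#' complement to the ratio-constancy diagnostic.
#'
#' @param rate_table Tibble with columns `internal_conc_uM`,
#'   `external_conc_uM`, `rate_nmol_mg_min` and optionally `rate_sd`
#'   (inverse-variance weights). Requires at least 2 internal and 4 external
#'   concentrations.
#' @param alpha Significance level (default 0.05).
#'
#' @return A `mechanism_test` with `statistic` (F), `df` (c(1, n - 4)),
#'   `p_value`, `call`, and `fits`, a list with the fitted `ping_pong` and
#'   `sequential` parameter vectors and residual sums of squares.
#' @export
global_mechanism_fit <- function(rate_table, alpha = 0.05) {
  assert_cols(rate_table, c("internal_conc_uM", "external_conc_uM",
                            "rate_nmol_mg_min"), "rate_table")
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1)
  tab <- dplyr::filter(rate_table, .data$internal_conc_uM > 0,
                       is.finite(.data$rate_nmol_mg_min))
  a <- tab$external_conc_uM
  b <- tab$internal_conc_uM
  v <- tab$rate_nmol_mg_min
  if (length(unique(b)) < 2L) {
    stop_input("Singular design: at least 2 internal concentrations are required.")
  }
  if (length(unique(a)) < 4L) {
    stop_input("At least 4 external concentrations are required.")
  }
  n <- length(v)
  if (n < 6L) stop_input("Too few rate points for a 4-parameter surface fit.")
  w <- rep(1, n)
  if ("rate_sd" %in% names(tab) && all(is.finite(tab$rate_sd)) &&
      all(tab$rate_sd > 0)) {
    w <- 1 / tab$rate_sd^2
  }

  start_pp <- c(vmax = 1.2 * max(v), km_ext = median(a), km_int = median(b))
  pp <- fit_rate_surface(a, b, v, w, sequential = FALSE, start = start_pp)
  if (is.null(pp)) stop_input("Ping-pong surface fit failed to converge.")
  starts_seq <- list(
    c(pp$par, ki_ext = 1e-6),
    c(pp$par, ki_ext = unname(median(a)))
  )
  seq_fits <- purrr::compact(purrr::map(
    starts_seq, ~ fit_rate_surface(a, b, v, w, sequential = TRUE, start = .x)
  ))
  if (!length(seq_fits)) stop_input("Sequential surface fit failed to converge.")
  sq <- seq_fits[[which.min(purrr::map_dbl(seq_fits, "rss"))]]

  df2 <- n - 4L
  scale <- sum(w * v^2)
  delta <- max(pp$rss - sq$rss, 0)
  f_stat <- if (pp$rss <= scale * 1e-12) {
    0  # both laws fit to numerical precision; no evidence for the extra term
  } else {
    delta / (sq$rss / df2)
  }
  p <- pf(f_stat, 1, df2, lower.tail = FALSE)
  new_mechanism_test(
    method = "global_fit", statistic = f_stat, df = c(1L, df2), p_value = p,
    call = if (p < alpha) "sequential" else "ping_pong", alpha = alpha,
    fits = list(ping_pong = c(pp$par, rss = pp$rss),
                sequential = c(sq$par, rss = sq$rss))
  )
}

#' Classify the transport mechanism
#'
#' Combines the ratio-constancy test ([ratio_constancy_test()]) and the
#' nested global rate-law comparison ([global_mechanism_fit()]): when both
#' support the same mechanism that is the verdict; discordant tests yield
#' `"inconclusive"` with both statistics reported.
#'
#' @param set A `kmvmax_set` from [fit_mm_curves()].
#' @param rate_table Initial-rate table from [initial_rates_table()].
#' @param alpha Significance level applied to both tests (default 0.05).
#'
#' @return An object of class `mechanism_verdict`: `call` (`"ping_pong"`,
#'   `"sequential"`, or `"inconclusive"`), `ratio_test`, `global_fit`,
#'   `alpha`. Supports [tidy()] and [glance()].
#' @export
classify_mechanism <- function(set, rate_table, alpha = 0.05) {
  rt <- ratio_constancy_test(set, alpha = alpha)
  gf <- global_mechanism_fit(rate_table, alpha = alpha)
  call <- if (rt$call == gf$call) rt$call else "inconclusive"
  structure(
    list(call = call, ratio_test = rt, global_fit = gf, alpha = alpha),
    class = "mechanism_verdict"
  )
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat("<mechanism_verdict>\n")
  cat(sprintf("  call: %s (alpha = %g)\n", x$call, x$alpha))
  cat(sprintf("  ratio-constancy: X2 = %.4g (df %d), p = %.4g -> %s\n",
              x$ratio_test$statistic, x$ratio_test$df, x$ratio_test$p_value,
              x$ratio_test$call))
  cat(sprintf("  global fit:      F  = %.4g (df %s), p = %.4g -> %s\n",
              x$global_fit$statistic, paste(x$global_fit$df, collapse = ","),
              x$global_fit$p_value, x$global_fit$call))
  invisible(x)
}

#' Serialize a mechanism verdict to JSON
#'
#' @param verdict A `mechanism_verdict`.
#' @param path File path; `NULL` returns the JSON string.
#' @param provenance Optional named list recorded under `"provenance"`.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_verdict_json <- function(verdict, path = NULL, provenance = NULL) {
  if (!inherits(verdict, "mechanism_verdict")) {
    stop_input("`verdict` must be a mechanism_verdict.")
  }
  payload <- list(
    call = verdict$call,
    alpha = verdict$alpha,
    ratio_constancy = list(
      statistic = verdict$ratio_test$statistic,
      df = verdict$ratio_test$df,
      p_value = verdict$ratio_test$p_value,
      call = verdict$ratio_test$call,
      weighted_mean_ratio = verdict$ratio_test$weighted_mean,
      ratios = verdict$ratio_test$ratios
    ),
    global_fit = list(
      f_statistic = verdict$global_fit$statistic,
      df = verdict$global_fit$df,
      p_value = verdict$global_fit$p_value,
      call = verdict$global_fit$call,
      ping_pong = as.list(verdict$global_fit$fits$ping_pong),
      sequential = as.list(verdict$global_fit$fits$sequential)
    )
  )
  if (!is.null(provenance)) payload$provenance <- provenance
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
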