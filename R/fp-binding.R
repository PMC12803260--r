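# Fluorescence-polarization binding: background normalization and
# nonlinear least-squares fitting of the Hill equation
#   mP(c) = baseline + amplitude * c^h / (Kd^h + c^h)
# to a protein titration at constant labelled-RNA concentration.
# Free protein is approximated by total protein (no ligand-depletion
# correction), valid when Kd is much larger than the 10 nM RNA.

#' Background-normalize a titration series
#'
#' Subtracts the mean polarization of the background wells (labelled
#' RNA only, no protein) from every well.
#'
#' @param series Titration tibble with `well_type` and `mp_raw`
#'   columns, e.g. from [simulate_fp_titration()].
#' @return `series` with an `mp` column; the subtracted background
#'   mean is attached as attribute `background_mean`.
#' @export
fp_normalize <- function(series) {
  bg <- series$mp_raw[series$well_type == "background"]
  if (length(bg) == 0) abort("no background wells to normalize against")
  out <- series %>% mutate(mp = .data$mp_raw - mean(bg))
  attr(out, "background_mean") <- mean(bg)
  out
}

#' Fit the Hill binding model to a titration
#'
#' Least-squares fit of
#' `mP(c) = baseline + amplitude * c^h / (Kd^h + c^h)` by
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]). Initial values:
#' baseline = min(mP), amplitude = max - min, Kd = the concentration
#' whose response is nearest half-amplitude, h = 1. The Hill
#' coefficient is bounded to `h_bounds` and Kd to
#' (0, `kd_max_factor` * max concentration]. A fit is flagged
#' `non_binder` when the fitted amplitude is smaller than three times
#' the residual SD or Kd sits at its upper bound.
#'
#' @param series Tibble with `conc_nm` and a response column (`mp` if
#'   present, else `mp_raw`); rows with `well_type != "titration"` are
#'   ignored. Replicates are pooled into one fit.
#' @param h_bounds Allowed Hill-coefficient range (default 0.2-5).
#' @param kd_max_factor Upper Kd bound as a multiple of the highest
#'   concentration (default 10).
#' @return An object of class `hill_fit`; see [tidy()] and [glance()]
#'   methods.
#' @export
fit_hill <- function(series, h_bounds = c(0.2, 5), kd_max_factor = 10) {
  df <- series
  if ("well_type" %in% names(df)) {
    df <- df %>% filter(.data$well_type == "titration")
  }
  resp <- if ("mp" %in% names(df)) "mp" else "mp_raw"
  df <- tibble(conc = df$conc_nm, mp = df[[resp]]) %>%
    filter(.data$conc > 0, is.finite(.data$mp))
  cu <- sort(unique(df$conc))
  if (length(cu) < 6 || log10(max(cu) / min(cu)) < 2) {
    abort(paste0("a fit needs at least 6 concentrations spanning at least ",
                 "2 orders of magnitude"))
  }
  if (nrow(df) < 4) abort("fewer than 4 informative points")
  kd_max <- kd_max_factor * max(df$conc)
  baseline0 <- min(df$mp)
  amplitude0 <- max(df$mp) - min(df$mp)
  half <- baseline0 + amplitude0 / 2
  kd0 <- df$conc[which.min(abs(df$mp - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mp ~ baseline + amplitude * conc^h / (kd^h + conc^h),
      data = df,
      start = list(baseline = baseline0, amplitude = amplitude0,
                   kd = kd0, h = 1),
      lower = c(baseline = -Inf, amplitude = 0, kd = .Machine$double.eps,
                h = h_bounds[1]),
      upper = c(baseline = Inf, amplitude = Inf, kd = kd_max,
                h = h_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(kd = NA_real_, h = NA_real_, baseline = NA_real_,
           amplitude = NA_real_, rss = NA_real_, sigma = NA_real_,
           converged = FALSE, non_binder = NA, n = nrow(df), data = df,
           fit = NULL),
      class = "hill_fit"))
  }
  est <- coef(fit)
  rss <- sum(resid(fit)^2)
  sigma <- sqrt(rss / max(1, nrow(df) - 4))
  non_binder <- unname(est["amplitude"] < 3 * sigma ||
                         est["kd"] >= kd_max * (1 - 1e-6))
  structure(
    list(kd = unname(est["kd"]), h = unname(est["h"]),
         baseline = unname(est["baseline"]),
         amplitude = unname(est["amplitude"]),
         rss = rss, sigma = sigma,
         converged = isTRUE(fit$convInfo$isConv),
         non_binder = non_binder, n = nrow(df), data = df, fit = fit),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill binding fit\n")
  cat(sprintf("  Kd        %.4g nM\n", x$kd))
  cat(sprintf("  h         %.3g\n", x$h))
  cat(sprintf("  baseline  %.4g mP\n", x$baseline))
  cat(sprintf("  amplitude %.4g mP\n", x$amplitude))
  cat(sprintf("  n = %d points, RSS = %.4g, converged: %s, non-binder: %s\n",
              x$n, x$rss, x$converged, x$non_binder))
  invisible(x)
}

#' Tidy a Hill fit into one row per parameter
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("kd", "h", "baseline", "amplitude"),
         estimate = c(x$kd, x$h, x$baseline, x$amplitude))
}

#' One-row model summary of a Hill fit
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the estimates, RSS, residual SD, point
#'   count and the convergence / non-binder flags.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(kd = x$kd, h = x$h, baseline = x$baseline,
         amplitude = x$amplitude, rss = x$rss, sigma = x$sigma,
         nobs = x$n, converged = x$converged, non_binder = x$non_binder)
}

#' Plot a Hill fit: points and fitted curve on a log axis
#' @param object A `hill_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot(df, aes(x = .data$conc, y = .data$mp)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "protein concentration (nM)", y = "polarization (mP)") +
    theme_bw()
  if (!is.null(object$fit)) {
    grid <- tibble(conc = 10^seq(log10(min(df$conc)), log10(max(df$conc)),
                                 length.out = 200))
    grid$mp <- object$baseline + object$amplitude * grid$conc^object$h /
      (object$kd^object$h + grid$conc^object$h)
    p <- p + geom_line(data = grid, colour = "steelblue")
  }
  p
}
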