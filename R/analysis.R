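series_window <- function(series, window) {
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be c(start, end) with start < end", call. = FALSE)
  }
  sel <- series$bin_start_min >= window[1] & series$bin_start_min < window[2]
  if (!any(sel)) stop("window lies outside the series", call. = FALSE)
  series[sel, , drop = FALSE]
}

#' Baseline statistics of a binned series
#'
#' Arithmetic mean and sample standard deviation of the bin concentrations
#' in a window, used as the stable pre-event reference (for the benchmark
#' replay: minutes 0-15 of the tap-water phase, n = 15 bins).
#'
#' @param series A `binned_series` (aligned to the reactor frame).
#' @param window `c(start, end)` in minutes; bins with
#'   `start <= bin_start_min < end` are used.
#' @return An object of class `baseline_stats`: list with `mean`, `sd`, `n`,
#'   `window`.
#' @examples
#' s <- data.frame(bin_start_min = 0:14, concentration = rep(130.6, 15))
#' baseline_stats(s, c(0, 15))
#' @export
baseline_stats <- function(series, window = c(0, 15)) {
  sub <- series_window(series, window)
  if (nrow(sub) < 2) {
    stop("need at least 2 bins for baseline statistics", call. = FALSE)
  }
  structure(list(mean = mean(sub$concentration),
                 sd = stats::sd(sub$concentration),
                 n = nrow(sub),
                 window = window),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("Baseline %.1f +/- %.1f cells/ul (n = %d, minutes %g-%g)\n",
              x$mean, x$sd, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Detect the onset of a deviation from baseline
#'
#' Earliest bin at which `min_consecutive` consecutive bins exceed
#' `mean + k_sigma * sd` (or fall below `mean - k_sigma * sd`). With a zero
#' baseline standard deviation any deviation from the mean triggers. The
#' search starts at the end of the baseline window.
#'
#' @param series A `binned_series`.
#' @param baseline A [baseline_stats()] from the same series' pre-event
#'   window.
#' @param k_sigma Threshold multiple of the baseline standard deviation.
#' @param min_consecutive Consecutive out-of-band bins required.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return `bin_start_min` of the first deviating bin, or `NA` if none.
#' @examples
#' s <- data.frame(bin_start_min = 0:20,
#'                 concentration = c(rep(130, 15), rep(400, 6)))
#' detect_onset(s, baseline_stats(s, c(0, 15)))
#' @export
detect_onset <- function(series, baseline, k_sigma = 3,
                         min_consecutive = 2, direction = "both") {
  stopifnot(k_sigma >= 0, min_consecutive >= 1)
  cand <- series[series$bin_start_min >= baseline$window[2], , drop = FALSE]
  if (nrow(cand) == 0) return(NA_real_)
  hi <- baseline$mean + k_sigma * baseline$sd
  lo <- baseline$mean - k_sigma * baseline$sd
  out <- switch(direction,
                up = cand$concentration > hi,
                down = cand$concentration < lo,
                both = cand$concentration > hi | cand$concentration < lo,
                stop("direction must be both/up/down", call. = FALSE))
  if (baseline$sd == 0 && k_sigma > 0) {
    dev <- cand$concentration != baseline$mean
    out <- switch(direction,
                  up = cand$concentration > baseline$mean,
                  down = cand$concentration < baseline$mean,
                  both = dev)
  }
  run <- 0L
  for (i in seq_along(out)) {
    run <- if (out[i]) run + 1L else 0L
    if (run >= min_consecutive) {
      return(cand$bin_start_min[i - min_consecutive + 1L])
    }
  }
  NA_real_
}

#' Ordinary least-squares rate of concentration change
#'
#' Linear fit of concentration against bin midpoint time over a window;
#' quantifies e.g. the slow linear total-cell decline during chlorination
#' (-10.6 cells/ul/min in the benchmark experiment).
#'
#' @param series A `binned_series`.
#' @param window `c(start, end)` minutes.
#' @param bin_width_min Bin width used to place midpoints, min.
#' @return List with `slope` (cells/ul/min), `intercept`, `r_squared`, `n`.
#' @examples
#' s <- data.frame(bin_start_min = 0:15, concentration = 600 - 10.6 * (0:15))
#' fit_linear_rate(s, c(0, 16))$slope
#' @export
fit_linear_rate <- function(series, window, bin_width_min = 1) {
  sub <- series_window(series, window)
  if (nrow(sub) < 3) stop("need at least 3 bins for a rate fit",
                          call. = FALSE)
  t <- sub$bin_start_min + bin_width_min / 2
  fit <- stats::lm(sub$concentration ~ t)
  tss <- sum((sub$concentration - mean(sub$concentration))^2)
  rss <- sum(stats::residuals(fit)^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       n = nrow(sub))
}

#' Fit an exponential washout to a binned series
#'
#' Nonlinear least squares for `c(t) = a + b * exp(-r * (t - t0))`, the
#' perfectly-mixed-reactor washout; `t0` is the window start. Starting
#' values come from a log-linear fit of the excess over `floor_guess`.
#' Non-convergence (or a degenerate, flat series) returns
#' `converged = FALSE` with a diagnostic message instead of an error.
#'
#' @param series A `binned_series`.
#' @param window `c(start, end)` minutes.
#' @param floor_guess Initial guess of the asymptote, cells/ul.
#' @param bin_width_min Bin width for midpoints, min.
#' @return List with `converged`, `rate` (min^-1), `asymptote`, `amplitude`,
#'   `rss`, `n`, `message`.
#' @examples
#' t <- 0:34
#' s <- data.frame(bin_start_min = t,
#'                 concentration = 130.6 + 424 * exp(-0.2 * (t + 0.5)))
#' fit_washout(s, c(0, 35), floor_guess = 130)$rate
#' @export
fit_washout <- function(series, window, floor_guess = 130,
                        bin_width_min = 1) {
  sub <- series_window(series, window)
  if (nrow(sub) < 4) stop("need at least 4 bins for a washout fit",
                          call. = FALSE)
  t <- sub$bin_start_min + bin_width_min / 2 - window[1]
  y <- sub$concentration
  fail <- function(msg) list(converged = FALSE, rate = NA_real_,
                             asymptote = NA_real_, amplitude = NA_real_,
                             rss = NA_real_, n = nrow(sub), message = msg)
  if (stats::sd(y) < 1e-10) {
    return(fail("series is constant; washout rate unidentifiable"))
  }
  excess <- y - floor_guess
  pos <- excess > 0
  if (sum(pos) < 3) {
    return(fail("too few bins above the asymptote guess"))
  }
  lf <- stats::lm(log(excess[pos]) ~ t[pos])
  start <- list(a = floor_guess,
                b = exp(unname(stats::coef(lf)[1])),
                r = max(-unname(stats::coef(lf)[2]), 1e-3))
  fit <- tryCatch(
    stats::nls(y ~ a + b * exp(-r * t), start = start,
               algorithm = "port",
               lower = c(a = 0, b = 0, r = 1e-6),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(fail(paste("nls failed:", conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  list(converged = TRUE, rate = unname(cf["r"]),
       asymptote = unname(cf["a"]), amplitude = unname(cf["b"]),
       rss = sum(stats::residuals(fit)^2), n = nrow(sub),
       message = "ok")
}

#' Percent reduction between two concentrations
#'
#' `100 * (1 - after / before)`; the benchmark intact-cell collapse from
#' 383.3 to 19.6 cells/ul is a ~95 % reduction.
#'
#' @param before,after Concentrations; `before` must be > 0.
#' @return Percent reduction.
#' @examples
#' percent_reduction(383.3, 19.6)
#' @export
percent_reduction <- function(before, after) {
  if (any(before <= 0)) stop("'before' must be > 0", call. = FALSE)
  100 * (1 - after / before)
}

#' Fold increase of a peak over a baseline
#'
#' Ratio and nearest-integer fold; the benchmark total-cell peak
#' (679.4 over 130.6 cells/ul) is a fivefold increase.
#'
#' @param peak,baseline Concentrations; `baseline` must be > 0.
#' @return List with `ratio` and `fold` (nearest integer).
#' @examples
#' fold_increase(679.4, 130.6)
#' @export
fold_increase <- function(peak, baseline) {
  if (any(baseline <= 0)) stop("'baseline' must be > 0", call. = FALSE)
  ratio <- peak / baseline
  list(ratio = ratio, fold = round(ratio))
}

#' Reactor volume changes over an elapsed time
#'
#' `dilution_rate * elapsed`: the number of reactor volumes exchanged.
#'
#' @param dilution_rate Dilution rate, min^-1.
#' @param elapsed Elapsed time, min.
#' @return Number of volume changes.
#' @examples
#' volume_changes(0.2, 15)  # three volume changes
#' @export
volume_changes <- function(dilution_rate, elapsed) {
  stopifnot(dilution_rate >= 0, elapsed >= 0)
  dilution_rate * elapsed
}

#' Derived summary quantities
#'
#' Bundles [percent_reduction()], [fold_increase()] and [volume_changes()]
#' for whichever argument pairs are supplied.
#'
#' @param before,after Pre/post concentrations for the percent reduction.
#' @param peak,baseline Peak and baseline for the fold increase.
#' @param dilution_rate,elapsed Dilution rate and elapsed time for volume
#'   changes.
#' @return Named list of the computed quantities.
#' @examples
#' derived_quantities(before = 383.3, after = 19.6,
#'                    peak = 679.4, baseline = 130.6)
#' @export
derived_quantities <- function(before = NULL, after = NULL,
                               peak = NULL, baseline = NULL,
                               dilution_rate = NULL, elapsed = NULL) {
  out <- list()
  if (!is.null(before) && !is.null(after)) {
    out$percent_reduction <- percent_reduction(before, after)
  }
  if (!is.null(peak) && !is.null(baseline)) {
    fi <- fold_increase(peak, baseline)
    out$fold_ratio <- fi$ratio
    out$fold <- fi$fold
  }
  if (!is.null(dilution_rate) && !is.null(elapsed)) {
    out$volume_changes <- volume_changes(dilution_rate, elapsed)
  }
  out
}

#' Compare a measured series against a predicted trajectory
#'
#' Interpolates the prediction to the measured bin midpoints, and reports
#' per-bin residuals (measured - predicted), RMSE, the maximum absolute
#' residual, and the integer-bin lag that maximizes agreement (minimum RMSE
#' over shifts of the measured series), mirroring the measured-versus-
#' calculated comparison of the benchmark experiment.
#'
#' @param measured A `binned_series` aligned to the reactor frame.
#' @param predicted An `rtfcm_trajectory`.
#' @param column Trajectory column to compare against, default `"tcc"`.
#' @param max_lag Largest lag magnitude searched, bins.
#' @param bin_width_min Bin width, min.
#' @return An object of class `comparison_report`: list with `residuals`
#'   (`data.frame` of `bin_start_min`, `measured`, `predicted`, `residual`),
#'   `rmse`, `max_abs_residual`, `lag_min`.
#' @examples
#' tr <- predict_tcc_series(experiment_config())
#' m <- data.frame(bin_start_min = 0:79,
#'                 concentration = trajectory_interp(tr, 0:79 + 0.5))
#' compare_to_prediction(m, tr)$rmse  # 0
#' @export
compare_to_prediction <- function(measured, predicted, column = "tcc",
                                  max_lag = 5, bin_width_min = 1) {
  mid <- measured$bin_start_min + bin_width_min / 2
  lo <- min(predicted$time_min); hi <- max(predicted$time_min)
  keep <- mid >= lo & mid <= hi
  if (!any(keep)) stop("no overlap between measured and predicted grids",
                       call. = FALSE)
  mid <- mid[keep]
  meas <- measured$concentration[keep]
  pred <- stats::approx(predicted$time_min, predicted[[column]],
                        xout = mid)$y
  resid <- meas - pred
  rmse <- sqrt(mean(resid^2))

  lags <- -max_lag:max_lag
  lag_rmse <- vapply(lags, function(L) {
    shifted <- stats::approx(predicted$time_min, predicted[[column]],
                             xout = mid - L * bin_width_min, rule = 2)$y
    sqrt(mean((meas - shifted)^2))
  }, numeric(1))
  best <- lags[which.min(lag_rmse)]

  structure(list(
    residuals = data.frame(bin_start_min = measured$bin_start_min[keep],
                           measured = meas, predicted = pred,
                           residual = resid),
    rmse = rmse,
    max_abs_residual = max(abs(resid)),
    lag_min = best * bin_width_min
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "Measured vs predicted: RMSE %.2f cells/ul, max |residual| %.2f, lag %g min (n = %d bins)\n",
    x$rmse, x$max_abs_residual, x$lag_min, nrow(x$residuals)))
  invisible(x)
}

#' Interpolate a trajectory column (exported helper)
#'
#' @param trajectory An `rtfcm_trajectory`.
#' @param times Times, min.
#' @param column Column name.
#' @return Interpolated values.
#' @export
trajectory_interp <- function(trajectory, times, column = "tcc") {
  trajectory_at(trajectory, times, column)
}
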