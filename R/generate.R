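#' Expected cell events per acquisition window
#'
#' Expectation of the Poisson event count from a sample at concentration
#' `concentration`, after the 1:dilution staining admixture, flowing through
#' the detector for one window: `concentration / dilution * flow_rate *
#' window` (with ul/min and ms converted consistently). Background events
#' are excluded. At the default instrument settings 130.6 cells/ul yields
#' ~1.52 expected events per 100 ms, ~914 per minute.
#'
#' @param concentration Cell concentration in the reactor, cells/ul
#'   (vectorized).
#' @param instrument An [instrument_model()].
#' @param window_ms Window duration, ms.
#' @return Expected event count (same length as `concentration`).
#' @examples
#' expected_events_per_window(130.6, instrument_model(), 100)
#' @export
expected_events_per_window <- function(concentration,
                                       instrument = instrument_model(),
                                       window_ms = instrument$acquisition_resolution_ms) {
  if (any(concentration < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (window_ms <= 0) stop("window_ms must be > 0", call. = FALSE)
  concentration / instrument$staining_dilution_factor *
    instrument$cytometer_flow_rate / 60000 * window_ms
}

subpop_params <- function(populations, mode, subpopulation) {
  cl <- populations$clusters[[mode]]
  if (is.null(cl)) stop("unknown staining mode '", mode, "'", call. = FALSE)
  p <- cl[[subpopulation]]
  if (is.null(p)) {
    stop("unknown subpopulation '", subpopulation, "' for mode ", mode,
         call. = FALSE)
  }
  p
}

#' Sample fluorescence values for a subpopulation
#'
#' Draws `n` (FL1, FL3) pairs from the configured log10-normal cluster of a
#' subpopulation under a staining mode. `fl1_shift` moves the FL1 location
#' (in dex); the generator uses it for the slow chlorine-exposure drift of
#' SG-stained clusters.
#'
#' @param populations A [population_model()].
#' @param subpopulation One of `"lna"`, `"hna"`, `"damaged"` (SG+PI only),
#'   `"background"`.
#' @param mode Staining mode, `"SG"` or `"SG+PI"`.
#' @param n Number of events.
#' @param fl1_shift Additive shift of the FL1 log10 location, dex.
#' @param seed Optional RNG seed for stand-alone reproducible draws.
#' @return A `data.frame` with columns `fl1`, `fl3` (positive, finite).
#' @examples
#' x <- sample_fluorescence(population_model(), "lna", "SG", 5, seed = 1)
#' @export
sample_fluorescence <- function(populations, subpopulation, mode = "SG",
                                n, fl1_shift = 0, seed = NULL) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- subpop_params(populations, mode, subpopulation)
  if (n == 0) {
    return(data.frame(fl1 = numeric(0), fl3 = numeric(0)))
  }
  data.frame(
    fl1 = 10^stats::rnorm(n, p$fl1_mean + fl1_shift, p$fl1_sd),
    fl3 = 10^stats::rnorm(n, p$fl3_mean, p$fl3_sd)
  )
}

#' Generate a continuous flow-cytometry event stream
#'
#' Emulates the continuous staining prototype: for each acquisition window
#' (default 100 ms) a Poisson number of events is drawn per subpopulation,
#' with rates proportional to the reactor concentration `staining_delay_min`
#' minutes earlier (the plug-flow staining/incubation transit), divided by
#' the staining dilution. Under `"SG"` all cells are drawn as LNA/HNA
#' clusters weighted by the tap/wastewater origin mix; under `"SG+PI"` the
#' intact cells form the LNA/HNA clusters and membrane-damaged cells
#' (TCC - ICC) are emitted as a PI-positive, high-FL3 cluster. Background
#' noise events arrive at the instrument's background rate. Event time tags
#' are uniform within their window; the stream is returned time-sorted.
#'
#' Acquisition time 0 corresponds to reactor time `-staining_delay_min`;
#' reactor times before the trajectory start are clamped to its first value
#' (the instrument was sampling steady tap water before the experiment).
#'
#' @param trajectory An `rtfcm_trajectory` covering
#'   `duration_min - staining_delay_min` minutes.
#' @param instrument An [instrument_model()].
#' @param populations A [population_model()].
#' @param staining_mode `"SG"` (total cells) or `"SG+PI"` (intact cells).
#' @param duration_min Acquisition span, min.
#' @param seed RNG seed; identical seeds give identical streams.
#' @return An object of class `event_stream`: list with `staining_mode`,
#'   `events` (`data.frame` of `time_ms`, `fl1`, `fl3`), `instrument`,
#'   `duration_min`, `seed`.
#' @examples
#' tr <- predict_tcc_series(experiment_config(total_duration = 46))
#' es <- generate_event_stream(tr, duration_min = 2, seed = 1)
#' nrow(es$events)  # ~1800 tap-water events in 2 min
#' @export
generate_event_stream <- function(trajectory,
                                  instrument = instrument_model(),
                                  populations = population_model(),
                                  staining_mode = c("SG", "SG+PI"),
                                  duration_min,
                                  seed) {
  staining_mode <- match.arg(staining_mode)
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  set.seed(seed)
  res_ms <- instrument$acquisition_resolution_ms
  n_win <- round(duration_min * 60000 / res_ms)
  if (n_win < 1) stop("duration too short for one window", call. = FALSE)
  win_start <- (seq_len(n_win) - 1) * res_ms
  # reactor time sampled by each window (midpoint), min
  t_reactor <- (win_start + res_ms / 2) / 60000 - instrument$staining_delay_min
  if (max(t_reactor) > max(trajectory$time_min) + 1e-9) {
    stop("trajectory shorter than acquisition span plus staining delay",
         call. = FALSE)
  }

  tcc <- trajectory_at(trajectory, t_reactor, "tcc")
  icc <- trajectory_at(trajectory, t_reactor, "icc")
  fww <- trajectory_at(trajectory, t_reactor, "wastewater_fraction")
  # cumulative chlorine exposure (minutes above the 0.05 mg/l detection
  # limit) drives the cosmetic SG FL1 drift
  cl_traj <- trajectory$chlorine_mg_l > 0.05
  dt <- diff(trajectory$time_min)
  exposure_grid <- c(0, cumsum(cl_traj[-length(cl_traj)] * dt))
  exposure <- stats::approx(trajectory$time_min, exposure_grid,
                            xout = pmax(t_reactor, min(trajectory$time_min)),
                            rule = 2)$y

  if (staining_mode == "SG") {
    p_lna <- ((1 - fww) * populations$pct_lna_tap_tcc +
                fww * populations$pct_lna_wastewater) / 100
    conc <- list(lna = tcc * p_lna, hna = tcc * (1 - p_lna))
    drift <- -populations$fl1_drift_rate * exposure
  } else {
    p_lna <- ((1 - fww) * populations$pct_lna_tap_icc +
                fww * populations$pct_lna_wastewater) / 100
    conc <- list(lna = icc * p_lna, hna = icc * (1 - p_lna),
                 damaged = pmax(tcc - icc, 0))
    drift <- rep(0, n_win)
  }

  pieces <- vector("list", length(conc) + 1L)
  for (k in seq_along(conc)) {
    pop <- names(conc)[k]
    lambda <- expected_events_per_window(conc[[pop]], instrument, res_ms)
    counts <- stats::rpois(n_win, lambda)
    n_ev <- sum(counts)
    if (n_ev == 0) {
      pieces[[k]] <- data.frame(time_ms = numeric(0), fl1 = numeric(0),
                                fl3 = numeric(0))
      next
    }
    widx <- rep.int(seq_len(n_win), counts)
    prm <- subpop_params(populations, staining_mode, pop)
    shift <- if (pop %in% c("lna", "hna")) drift[widx] else 0
    pieces[[k]] <- data.frame(
      time_ms = win_start[widx] + stats::runif(n_ev, 0, res_ms),
      fl1 = 10^stats::rnorm(n_ev, prm$fl1_mean + shift, prm$fl1_sd),
      fl3 = 10^stats::rnorm(n_ev, prm$fl3_mean, prm$fl3_sd)
    )
  }
  # background noise events, uniform in time
  n_bg <- stats::rpois(1, instrument$background_event_rate *
                         duration_min * 60)
  bg <- subpop_params(populations, staining_mode, "background")
  pieces[[length(pieces)]] <- data.frame(
    time_ms = stats::runif(n_bg, 0, n_win * res_ms),
    fl1 = 10^stats::rnorm(n_bg, bg$fl1_mean, bg$fl1_sd),
    fl3 = 10^stats::rnorm(n_bg, bg$fl3_mean, bg$fl3_sd)
  )

  events <- do.call(rbind, pieces)
  events <- events[order(events$time_ms), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(staining_mode = staining_mode,
                 events = events,
                 instrument = instrument,
                 duration_min = duration_min,
                 seed = seed),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("Event stream [%s]: %d events over %g min (seed %s)\n",
              x$staining_mode, nrow(x$events), x$duration_min,
              format(x$seed)))
  invisible(x)
}
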