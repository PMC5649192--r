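#' Volume fraction contributed by a syringe addition
#'
#' Share (v/v) of the reactor content that originates from an addition after
#' `elapsed` minutes of pumping at `rate` into a reactor initially holding
#' `initial_volume`. One minute of wastewater addition at 3 ml/min into
#' 500 ml is a 0.6 % (v/v) share.
#'
#' @param rate Addition rate, ml/min.
#' @param elapsed Time since the addition started, min.
#' @param initial_volume Reactor volume before the addition, ml.
#' @return Dimensionless fraction in \[0, 1\].
#' @examples
#' volume_fraction_added(3, 1, 500)  # ~0.006
#' @export
volume_fraction_added <- function(rate, elapsed, initial_volume) {
  stopifnot(rate >= 0, elapsed >= 0, initial_volume >= 0)
  added <- rate * elapsed
  total <- initial_volume + added
  if (total <= 0) {
    stop("degenerate input: total volume is zero", call. = FALSE)
  }
  added / total
}

#' Washout of a perfectly mixed reactor
#'
#' Concentration in a continuously stirred flow-through reactor `t` minutes
#' after switching to an inflow of concentration `c_in`:
#' `c_in + (c0 - c_in) * exp(-D * t)` with dilution rate `D` (flow rate over
#' reactor volume). Excess concentration falls to `exp(-3)` (~5 %) of its
#' initial value after three volume changes.
#'
#' @param c0 Concentration at the switch, cells/ul (any unit).
#' @param c_in Inflow concentration, same unit.
#' @param dilution_rate Dilution rate D, min^-1.
#' @param t Time since the switch, min (vectorized).
#' @return Concentration at time `t`, same unit as `c0`.
#' @examples
#' washout_concentration(679.4, 130.6, 0.2, 0:35)
#' @export
washout_concentration <- function(c0, c_in, dilution_rate, t) {
  stopifnot(dilution_rate >= 0)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  c_in + (c0 - c_in) * exp(-dilution_rate * t)
}

#' Nominal chlorine dose concentration
#'
#' Free chlorine concentration reached in the reactor by pumping a
#' hypochlorite stock, ignoring demand: dosed mass over the reference
#' volume. The benchmark dose (72 mg/l stock, 2.5 ml/min, 5 min, 500 ml)
#' is 1.8 mg/l.
#'
#' @param stock Stock concentration, mg/l.
#' @param rate Pump rate, ml/min.
#' @param duration Pumping time, min.
#' @param reference_volume Volume the dose is referenced to, ml.
#' @return Concentration, mg/l.
#' @examples
#' chlorine_dose_concentration(72, 2.5, 5, 500)  # 1.8
#' @export
chlorine_dose_concentration <- function(stock, rate, duration,
                                        reference_volume) {
  stopifnot(stock >= 0, rate >= 0, duration >= 0)
  if (reference_volume <= 0) {
    stop("reference_volume must be > 0", call. = FALSE)
  }
  stock * rate * duration / reference_volume
}

phase_times <- function(config) {
  p <- config$phase_start_times
  list(baseline = p[1],
       contam_start = p[2],
       contam_end = p[2] + config$contaminant_duration,
       chlor_start = p[3],
       chlor_end = p[3] + config$chlorine_duration,
       washout = p[4],
       end = config$total_duration)
}

#' Predicted cell-concentration trajectory (pure mixing)
#'
#' The four-phase mass-balance prediction at the configured grid
#' resolution, assuming perfect mixing and no effect of chlorine on cell
#' counts: (1) constant tap-water baseline; (2) batch mixing during the
#' wastewater addition, `C(t) = (V0 C0 + r tau C_in) / (V0 + r tau)`;
#' (3) constant plateau; (4) exponential washout toward the tap-water level
#' at the dilution rate `flowthrough_rate / initial_volume` (0.2 min^-1 for
#' the defaults).
#'
#' Following the original calculation, the dilution rate and the chlorine
#' dose are referenced to the nominal reactor size (`initial_volume`); the
#' small injected volumes (+15 ml, +12.5 ml) do not re-dilute the plateau.
#' `simulate_experiment()` offers a fully volume-tracking alternative.
#'
#' @param config An [experiment_config()].
#' @param washout_from Anchor of the washout branch: `"plateau"` (default,
#'   the predicted plateau) or a numeric concentration pair
#'   `c(tcc, icc)` to start the washout from (e.g. measured values).
#' @return A `data.frame` of class `rtfcm_trajectory` with columns
#'   `time_min`, `volume_ml`, `tcc`, `icc`, `chlorine_mg_l`,
#'   `wastewater_fraction`, `dilution_rate`.
#' @examples
#' tr <- predict_tcc_series(experiment_config())
#' tr[tr$time_min %in% c(10, 20, 40, 60), ]
#' @export
predict_tcc_series <- function(config = experiment_config(),
                               washout_from = "plateau") {
  config <- validate_experiment_config(config)
  ph <- phase_times(config)
  tt <- seq(ph$baseline, ph$end, by = config$time_step)
  V0 <- config$initial_volume
  r <- config$contaminant_rate
  D <- config$flowthrough_rate / V0

  mix <- function(c0, c_in, tau) {
    (V0 * c0 + r * tau * c_in) / (V0 + r * tau)
  }
  tau_add <- pmin(pmax(tt - ph$contam_start, 0), config$contaminant_duration)
  tcc <- mix(config$tap_tcc, config$contaminant_tcc, tau_add)
  icc <- mix(config$tap_icc, config$contaminant_icc, tau_add)
  # wastewater-origin concentration shares the same mixing arithmetic with
  # zero tap contribution
  ww <- mix(0, config$contaminant_tcc, tau_add)

  plateau_tcc <- mix(config$tap_tcc, config$contaminant_tcc,
                     config$contaminant_duration)
  plateau_icc <- mix(config$tap_icc, config$contaminant_icc,
                     config$contaminant_duration)
  plateau_ww <- mix(0, config$contaminant_tcc, config$contaminant_duration)

  anchor_tcc <- plateau_tcc
  anchor_icc <- plateau_icc
  if (is.numeric(washout_from)) {
    anchor_tcc <- washout_from[1]
    anchor_icc <- if (length(washout_from) > 1) washout_from[2] else NA_real_
  } else if (!identical(washout_from, "plateau")) {
    stop("washout_from must be \"plateau\" or a numeric anchor",
         call. = FALSE)
  }

  wo <- tt > ph$washout
  tw <- tt[wo] - ph$washout
  tcc[wo] <- washout_concentration(anchor_tcc, config$tap_tcc, D, tw)
  icc[wo] <- washout_concentration(anchor_icc, config$tap_icc, D, tw)
  ww[wo] <- washout_concentration(plateau_ww, 0, D, tw)

  # nominal chlorine: linear dose ramp, then first-order-free plateau, then
  # washout (no demand term in the prediction)
  dose_tau <- pmin(pmax(tt - ph$chlor_start, 0), config$chlorine_duration)
  cl <- chlorine_dose_concentration(config$chlorine_stock,
                                    config$chlorine_rate, dose_tau, V0)
  cl[wo] <- washout_concentration(cl[sum(!wo)], 0, D, tw)

  out <- data.frame(
    time_min = tt,
    volume_ml = V0,
    tcc = tcc,
    icc = icc,
    chlorine_mg_l = cl,
    wastewater_fraction = ifelse(tcc > 0, ww / tcc, 0),
    dilution_rate = ifelse(wo, D, 0)
  )
  attr(out, "config") <- config
  class(out) <- c("rtfcm_trajectory", "data.frame")
  out
}

#' Simulate the full experiment with disinfection kinetics
#'
#' Extends the pure mixing prediction with first-order intact-cell
#' inactivation and chlorine demand, the empirical linear total-cell loss
#' during batch chlorination, and origin-labeled cell balances yielding the
#' wastewater-origin fraction. Integrated with a fixed-step classical RK4
#' scheme at sub-minute resolution and reported on the configured grid.
#'
#' With all kinetic rates zero and `track_volume = FALSE` the trajectory
#' reduces exactly to [predict_tcc_series()]. With `track_volume = TRUE`
#' the injected syringe volumes grow the reactor volume, injections dilute
#' all species, and the washout dilution rate uses the true final volume;
#' this mode conserves cell numbers exactly and backs the conservation
#' tests.
#'
#' @param config An [experiment_config()].
#' @param kinetics A [kinetic_params()].
#' @param step Integration step, min. Must divide `config$time_step`.
#' @param track_volume Track injected volumes (see Details).
#' @return A `data.frame` of class `rtfcm_trajectory` with the columns of
#'   [predict_tcc_series()] plus `cum_outflow_cells` (cells washed out of
#'   the reactor, absolute count).
#' @examples
#' tr <- simulate_experiment(experiment_config(), kinetic_params())
#' min(tr$icc[tr$time_min >= 34 & tr$time_min <= 45])  # collapsed ICC
#' @export
simulate_experiment <- function(config = experiment_config(),
                                kinetics = kinetic_params(),
                                step = 0.01,
                                track_volume = FALSE) {
  config <- validate_experiment_config(config)
  if (!inherits(kinetics, "kinetic_params")) {
    kinetics <- do.call(kinetic_params, as.list(kinetics))
  }
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  n_sub <- round(config$time_step / step)
  if (n_sub < 1 || abs(n_sub * step - config$time_step) > 1e-9) {
    stop("step must evenly divide time_step", call. = FALSE)
  }
  ph <- phase_times(config)
  V0 <- config$initial_volume

  # state: volume, tcc, icc, ww-origin tcc, chlorine, cumulative outflow
  # (cells/ul * ml; multiply by 1000 for absolute cells)
  # phase membership is frozen per substep (classified at the substep
  # midpoint) so no RK4 stage straddles a phase boundary
  deriv <- function(t, s, in_contam, in_chlor, in_flow) {
    V <- s[1]; Ct <- s[2]; Ci <- s[3]; Cw <- s[4]; Cl <- s[5]
    dV <- 0; dCt <- 0; dCi <- 0; dCw <- 0; dCl <- 0; dOut <- 0

    if (in_contam) {
      r <- config$contaminant_rate
      Vmix <- if (track_volume) V else V0 + r * (t - ph$contam_start)
      dCt <- dCt + r * (config$contaminant_tcc - Ct) / Vmix
      dCi <- dCi + r * (config$contaminant_icc - Ci) / Vmix
      dCw <- dCw + r * (config$contaminant_tcc - Cw) / Vmix
      if (track_volume) dV <- dV + r
    }
    if (in_chlor) {
      rc <- config$chlorine_rate
      if (track_volume) {
        dCl <- dCl + rc * (config$chlorine_stock - Cl) / V
      } else {
        # fixed-volume convention: dose accumulates linearly to the nominal
        # stock * rate * duration / V0 concentration
        dCl <- dCl + rc * config$chlorine_stock / V0
      }
      if (track_volume) {
        dV <- dV + rc
        dCt <- dCt - rc * Ct / V
        dCi <- dCi - rc * Ci / V
        dCw <- dCw - rc * Cw / V
      }
    }
    if (in_flow) {
      D <- config$flowthrough_rate / (if (track_volume) V else V0)
      dCt <- dCt + D * (config$tap_tcc - Ct)
      dCi <- dCi + D * (config$tap_icc - Ci)
      dCw <- dCw - D * Cw
      dCl <- dCl - D * Cl
      dOut <- config$flowthrough_rate * Ct
    }
    dCl <- dCl - kinetics$chlorine_demand_rate * Cl
    if (Cl > kinetics$kill_threshold) {
      dCi <- dCi - kinetics$icc_kill_rate * Ci
      if (!in_flow && Ct > 0) {
        # empirical DNA-damage signal loss, observed only in batch operation
        dec <- kinetics$tcc_decay_rate
        dCt <- dCt - dec
        dCw <- dCw - dec * Cw / Ct
      }
    }
    c(dV, dCt, dCi, dCw, dCl, dOut)
  }

  tt <- seq(ph$baseline, ph$end, by = config$time_step)
  n_out <- length(tt)
  state <- c(V0, config$tap_tcc, config$tap_icc, 0, 0, 0)
  res <- matrix(NA_real_, n_out, 6)
  res[1, ] <- state
  t <- tt[1]
  for (i in seq_len(n_out - 1L)) {
    for (j in seq_len(n_sub)) {
      tm <- t + step / 2
      in_contam <- tm >= ph$contam_start && tm < ph$contam_end
      in_chlor <- tm >= ph$chlor_start && tm < ph$chlor_end
      in_flow <- tm >= ph$washout
      k1 <- deriv(t, state, in_contam, in_chlor, in_flow)
      k2 <- deriv(tm, state + step / 2 * k1, in_contam, in_chlor, in_flow)
      k3 <- deriv(tm, state + step / 2 * k2, in_contam, in_chlor, in_flow)
      k4 <- deriv(t + step, state + step * k3, in_contam, in_chlor, in_flow)
      state <- state + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
      # physical floors and ordering: concentrations nonnegative, intact and
      # wastewater-origin pools bounded by the total pool
      state[2] <- max(state[2], 0)
      state[3] <- min(max(state[3], 0), state[2])
      state[4] <- min(max(state[4], 0), state[2])
      state[5] <- max(state[5], 0)
    }
    t <- tt[i + 1L]  # avoid drift in phase-boundary comparisons
    res[i + 1L, ] <- state
  }

  out <- data.frame(
    time_min = tt,
    volume_ml = res[, 1],
    tcc = res[, 2],
    icc = res[, 3],
    chlorine_mg_l = res[, 5],
    wastewater_fraction = ifelse(res[, 2] > 0, res[, 4] / res[, 2], 0),
    dilution_rate = ifelse(
      tt > ph$washout,
      config$flowthrough_rate / (if (track_volume) res[, 1] else V0), 0),
    cum_outflow_cells = res[, 6] * 1000
  )
  attr(out, "config") <- config
  attr(out, "kinetics") <- kinetics
  class(out) <- c("rtfcm_trajectory", "data.frame")
  out
}

#' Interpolate a trajectory column at arbitrary times
#'
#' Linear interpolation used by the event-stream generator; times before the
#' trajectory start are clamped to the initial value (the instrument samples
#' steady pre-experiment tap water), times beyond the end are an error.
#'
#' @param trajectory An `rtfcm_trajectory`.
#' @param times Times to interpolate at, min.
#' @param column Trajectory column name.
#' @return Numeric vector of interpolated values.
#' @keywords internal
trajectory_at <- function(trajectory, times, column = "tcc") {
  tmax <- max(trajectory$time_min)
  if (any(times > tmax + 1e-9)) {
    stop("trajectory does not cover requested times (ends at ",
         tmax, " min)", call. = FALSE)
  }
  stats::approx(trajectory$time_min, trajectory[[column]],
                xout = pmax(times, min(trajectory$time_min)),
                rule = 2)$y
}
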