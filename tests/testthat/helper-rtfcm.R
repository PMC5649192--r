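# shared fixtures: small configs and a constant-concentration trajectory
# builder used across generator/pipeline tests

constant_trajectory <- function(tcc, icc = tcc * 0.76, duration_min = 30,
                                wastewater_fraction = 0) {
  tt <- seq(0, duration_min, by = 1)
  out <- data.frame(
    time_min = tt, volume_ml = 500,
    tcc = rep(tcc, length(tt)), icc = rep(icc, length(tt)),
    chlorine_mg_l = 0,
    wastewater_fraction = rep(wastewater_fraction, length(tt)),
    dilution_rate = 0
  )
  class(out) <- c("rtfcm_trajectory", "data.frame")
  out
}

# instrument with no noise events and no staining delay: isolates the
# cell-event Poisson process
clean_instrument <- function(...) {
  instrument_model(background_event_rate = 0, staining_delay_min = 0, ...)
}

default_phase_times <- function(cfg = experiment_config()) {
  p <- cfg$phase_start_times
  list(contam_start = p[2], contam_end = p[2] + cfg$contaminant_duration,
       chlor_start = p[3], chlor_end = p[3] + cfg$chlorine_duration,
       washout = p[4], end = cfg$total_duration)
}
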