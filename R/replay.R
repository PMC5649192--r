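#' Run the full in-silico replay of the experiment
#'
#' Orchestrates the whole chain: simulate the reactor (with disinfection
#' kinetics), generate continuous event streams for both staining modes,
#' gate and bin them into 1-min series, align them to the reactor frame,
#' run the analyses (baseline, onset, chlorination rate, washout fit,
#' derived quantities) and compare the measured total-cell series against
#' the pure-mixing prediction. All outputs are written under `out_dir`
#' together with a manifest carrying per-file MD5 checksums; everything is
#' deterministic for a fixed `(config, seed)`.
#'
#' The comparison anchors the prediction's washout branch at the measured
#' concentration of the first washout bin (see the methods vignette): the
#' chlorination decline is deliberately absent from the prediction, and
#' anchoring stops it from propagating an offset through the washout.
#'
#' @param config An [experiment_config()].
#' @param kinetics A [kinetic_params()].
#' @param instrument An [instrument_model()].
#' @param populations A [population_model()].
#' @param gates A [gate_set()].
#' @param seed Master seed; per-stream substream seeds are derived from it.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (files + checksums), the two
#'   aligned `binned_series` (`tcc_series`, `icc_series`), `trajectory`,
#'   `prediction`, `analysis` (named list) and `comparison`.
#' @examples
#' \donttest{
#' res <- run_replay(seed = 1, out_dir = tempfile("replay"))
#' res$analysis$tcc_onset_min
#' }
#' @export
run_replay <- function(config = experiment_config(),
                       kinetics = kinetic_params(),
                       instrument = instrument_model(),
                       populations = population_model(),
                       gates = gate_set(),
                       seed = 1,
                       out_dir = tempfile("rtfcm_replay")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed) %% 2100000000L

  trajectory <- simulate_experiment(config, kinetics)
  prediction <- predict_tcc_series(config)

  acq_min <- config$total_duration + instrument$staining_delay_min
  sg <- generate_event_stream(trajectory, instrument, populations,
                              "SG", acq_min, seed = seed + 1L)
  sgpi <- generate_event_stream(trajectory, instrument, populations,
                                "SG+PI", acq_min, seed = seed + 2L)

  tcc_series <- align_series(bin_stream(sg, gates, instrument),
                             instrument$staining_delay_min)
  icc_series <- align_series(bin_stream(sgpi, gates, instrument),
                             instrument$staining_delay_min)

  ph <- phase_times(config)
  base_window <- c(ph$baseline, ph$contam_start)
  tcc_base <- baseline_stats(tcc_series, base_window)
  icc_base <- baseline_stats(icc_series, base_window)

  tcc_onset <- detect_onset(tcc_series, tcc_base)
  icc_onset <- detect_onset(icc_series, icc_base)
  # first bin with collapsed intact counts after chlorination starts
  post <- icc_series[icc_series$bin_start_min >= ph$chlor_start &
                       icc_series$bin_start_min < ph$washout, ]
  icc_collapse <- if (any(post$concentration < 30)) {
    post$bin_start_min[which(post$concentration < 30)[1]]
  } else NA_real_

  chlor_window <- c(ph$chlor_start + 1, ph$washout + 1)
  tcc_rate <- fit_linear_rate(tcc_series, chlor_window)
  washout_window <- c(ph$washout + 1, ph$end)
  tcc_washout <- fit_washout(tcc_series, washout_window,
                             floor_guess = config$tap_tcc)

  plateau <- icc_series[icc_series$bin_start_min >= ph$contam_end + 1 &
                          icc_series$bin_start_min < ph$chlor_start, ]
  peak_tcc <- max(tcc_series$concentration[
    tcc_series$bin_start_min >= ph$baseline])
  collapse_from <- if (is.na(icc_collapse)) ph$washout else icc_collapse
  derived <- derived_quantities(
    before = mean(plateau$concentration),
    after = mean(post$concentration[post$bin_start_min >= collapse_from]),
    peak = peak_tcc, baseline = tcc_base$mean)
  derived$icc_fold_ratio <- mean(plateau$concentration) / icc_base$mean
  derived$icc_fold <- round(derived$icc_fold_ratio)

  anchor_bin <- tcc_series[tcc_series$bin_start_min == ph$washout, ]
  anchored_pred <- if (nrow(anchor_bin) == 1) {
    predict_tcc_series(config,
                       washout_from = c(anchor_bin$concentration, NA))
  } else prediction
  comparison <- compare_to_prediction(
    tcc_series[tcc_series$bin_start_min >= 0, ], anchored_pred)

  analysis <- list(
    tcc_baseline_mean = tcc_base$mean, tcc_baseline_sd = tcc_base$sd,
    icc_baseline_mean = icc_base$mean, icc_baseline_sd = icc_base$sd,
    baseline_n = tcc_base$n,
    tcc_onset_min = tcc_onset, icc_onset_min = icc_onset,
    icc_collapse_min = icc_collapse,
    tcc_chlorination_slope = tcc_rate$slope,
    washout_rate = tcc_washout$rate,
    washout_asymptote = tcc_washout$asymptote,
    washout_converged = tcc_washout$converged,
    icc_post_mean = mean(post$concentration),
    percent_reduction_icc = derived$percent_reduction,
    tcc_fold_ratio = derived$fold_ratio, tcc_fold = derived$fold,
    icc_fold_ratio = derived$icc_fold_ratio, icc_fold = derived$icc_fold,
    comparison_rmse = comparison$rmse,
    comparison_lag_min = comparison$lag_min,
    seed = seed
  )

  paths <- c(
    trajectory = "trajectory.csv",
    prediction = "prediction.csv",
    events_sg = "events_sg.csv",
    events_sgpi = "events_sgpi.csv",
    binned_tcc = "binned_tcc.csv",
    binned_icc = "binned_icc.csv",
    comparison = "comparison.csv",
    analysis = "analysis.json"
  )
  paths <- vapply(paths, function(p) file.path(out_dir, p), character(1))
  utils::write.csv(as.data.frame(trajectory), paths["trajectory"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(prediction), paths["prediction"],
                   row.names = FALSE)
  write_event_stream(sg, paths["events_sg"])
  write_event_stream(sgpi, paths["events_sgpi"])
  write_binned_series(tcc_series, paths["binned_tcc"])
  write_binned_series(icc_series, paths["binned_icc"])
  utils::write.csv(comparison$residuals, paths["comparison"],
                   row.names = FALSE)
  jsonlite::write_json(analysis, paths["analysis"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  all_files <- c(paths, meta_sg = paste0(paths[["events_sg"]], ".meta.json"),
                 meta_sgpi = paste0(paths[["events_sgpi"]], ".meta.json"))
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("rtfcm")),
    files = data.frame(stage = names(all_files),
                       path = basename(unname(all_files)),
                       md5 = unname(tools::md5sum(unname(all_files))),
                       row.names = NULL)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest,
                 trajectory = trajectory, prediction = prediction,
                 tcc_series = tcc_series, icc_series = icc_series,
                 analysis = analysis, comparison = comparison,
                 out_dir = out_dir))
}
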