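#' Reference measurements from the benchmark experiment
#'
#' The published summary numbers of the bench-scale contamination /
#' shock-chlorination experiment that the default configuration replays.
#' They serve as inputs (offline wastewater counts, chlorine grab samples)
#' and as anchors for tests and documentation; none of them is produced by
#' this package's computations.
#'
#' @return A `data.frame` with columns `key`, `value`, `unit`,
#'   `description`.
#' @examples
#' ref_value("chlorine_t35")
#' @export
reference_measurements <- function() {
  de <- function(...) data.frame(..., stringsAsFactors = FALSE)
  rbind(
    de(key = "tap_tcc_mean", value = 130.6, unit = "cells/ul",
       description = "tap-water baseline TCC mean (minutes 1-15, n = 15)"),
    de(key = "tap_tcc_sd", value = 8.3, unit = "cells/ul",
       description = "tap-water baseline TCC standard deviation"),
    de(key = "tap_icc_mean", value = 99.6, unit = "cells/ul",
       description = "tap-water baseline ICC mean (minutes 1-15, n = 15)"),
    de(key = "tap_icc_sd", value = 5.9, unit = "cells/ul",
       description = "tap-water baseline ICC standard deviation"),
    de(key = "baseline_n", value = 15, unit = "bins",
       description = "number of 1-min baseline bins"),
    de(key = "wastewater_tcc", value = 14700, unit = "cells/ul",
       description = "offline TCC of the 10-fold pre-diluted wastewater"),
    de(key = "pct_hna_wastewater", value = 61.3, unit = "%",
       description = "HNA share of raw wastewater bacteria"),
    de(key = "tcc_peak", value = 679.4, unit = "cells/ul",
       description = "maximum measured TCC (minute 30)"),
    de(key = "icc_plateau_mean", value = 383.3, unit = "cells/ul",
       description = "post-contamination ICC plateau mean"),
    de(key = "icc_plateau_sd", value = 10.6, unit = "cells/ul",
       description = "post-contamination ICC plateau standard deviation"),
    de(key = "icc_postchlorination_mean", value = 19.6, unit = "cells/ul",
       description = "collapsed ICC mean after chlorination (25 min window)"),
    de(key = "icc_postchlorination_sd", value = 3.7, unit = "cells/ul",
       description = "collapsed ICC standard deviation"),
    de(key = "tcc_decay_rate", value = 10.6, unit = "cells/ul/min",
       description = "linear TCC decline during chlorination (minutes 31-46)"),
    de(key = "chlorine_dose", value = 1.8, unit = "mg/l",
       description = "nominal initial free-chlorine concentration"),
    de(key = "chlorine_t35", value = 1.46, unit = "mg/l",
       description = "free chlorine grab sample, minute 35"),
    de(key = "chlorine_t45", value = 1.09, unit = "mg/l",
       description = "free chlorine grab sample, minute 45"),
    de(key = "chlorine_t55", value = 0.138, unit = "mg/l",
       description = "free chlorine grab sample, minute 55"),
    de(key = "chlorine_consumption_5min", value = 0.34, unit = "mg/l",
       description = "chlorine consumed in the first 5 min after dosing"),
    de(key = "chlorine_detection_limit", value = 0.05, unit = "mg/l",
       description = "DPD assay lower limit of the linear range"),
    de(key = "pct_lna_tap_tcc", value = 65, unit = "%",
       description = "LNA share of tap-water cells (TCC, minute 10)"),
    de(key = "pct_lna_contaminated_tcc", value = 29, unit = "%",
       description = "LNA share after contamination (TCC, minute 25)"),
    de(key = "pct_lna_tap_icc", value = 71, unit = "%",
       description = "LNA share of tap-water intact cells (minute 10)"),
    de(key = "pct_lna_contaminated_icc", value = 37, unit = "%",
       description = "LNA share of intact cells after contamination"),
    de(key = "pct_lna_chlorinated_tcc", value = 32, unit = "%",
       description = "LNA share during chlorination (TCC, minute 40)"),
    de(key = "tap_return_tcc", value = 140, unit = "cells/ul",
       description = "approximate TCC after washout to tap water"),
    de(key = "tap_return_icc", value = 95, unit = "cells/ul",
       description = "approximate ICC after washout recovery"),
    de(key = "dilution_rate", value = 0.2, unit = "1/min",
       description = "flow-through dilution rate (100 ml/min over 500 ml)")
  )
}

#' @rdname reference_measurements
#' @param key A key from [reference_measurements()].
#' @export
ref_value <- function(key) {
  tab <- reference_measurements()
  i <- match(key, tab$key)
  if (is.na(i)) {
    stop("unknown reference key '", key, "'; see reference_measurements()",
         call. = FALSE)
  }
  tab$value[i]
}

#' Chlorine grab-sample table
#'
#' The DPD colorimetric grab samples of the benchmark experiment: taken 10,
#' 20, 35, 40, 45, 50, 55 and 60 min after the start. Values below the
#' 0.05 mg/l detection limit are flagged, never encoded as 0; samples whose
#' numeric value was not published carry `NA` with `below_detection =
#' FALSE`.
#'
#' @return A `data.frame` with `time_min`, `chlorine_mg_l`,
#'   `below_detection`; attribute `detection_limit_mg_l`.
#' @examples
#' chlorine_samples()
#' @export
chlorine_samples <- function() {
  out <- data.frame(
    time_min = c(10, 20, 35, 40, 45, 50, 55, 60),
    chlorine_mg_l = c(NA, NA, 1.46, NA, 1.09, NA, 0.138, NA),
    below_detection = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  attr(out, "detection_limit_mg_l") <- 0.05
  out
}
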