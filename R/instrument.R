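#' Continuous flow-cytometer instrument model
#'
#' Parameters of the continuous staining/acquisition prototype: the sample
#' is drawn at 0.3 ml/min, mixed 1:1 with stain (dilution factor 2),
#' incubated for 10 min in a flowing loop (a pure time shift between reactor
#' and detector), and measured at 14 ul/min with events time-tagged at
#' 100 ms resolution. Events below the green-fluorescence (FL1) threshold of
#' 1000 instrument units are not counted as cells.
#'
#' @param cytometer_flow_rate Volumetric rate through the detector, ul/min.
#' @param acquisition_resolution_ms Width of an acquisition window, ms.
#' @param staining_dilution_factor Sample dilution by stain admixture
#'   (>= 1); the concentration estimator inverts the same factor.
#' @param staining_delay_min Staining/incubation transit time, min.
#' @param detection_threshold_fl1 Lower FL1 threshold, instrument units.
#' @param background_event_rate Rate of instrument/noise events (near or
#'   below threshold), events/s.
#' @return An object of class `instrument_model`.
#' @examples
#' instrument_model()
#' @export
instrument_model <- function(cytometer_flow_rate = 14,
                             acquisition_resolution_ms = 100,
                             staining_dilution_factor = 2,
                             staining_delay_min = 10,
                             detection_threshold_fl1 = 1000,
                             background_event_rate = 0.5) {
  m <- list(cytometer_flow_rate = cytometer_flow_rate,
            acquisition_resolution_ms = acquisition_resolution_ms,
            staining_dilution_factor = staining_dilution_factor,
            staining_delay_min = staining_delay_min,
            detection_threshold_fl1 = detection_threshold_fl1,
            background_event_rate = background_event_rate)
  for (f in names(m)) {
    v <- m[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("instrument field '", f, "' must be a single finite value >= 0",
           call. = FALSE)
    }
  }
  if (m$staining_dilution_factor < 1) {
    stop("staining_dilution_factor must be >= 1", call. = FALSE)
  }
  if (m$acquisition_resolution_ms <= 0 || m$cytometer_flow_rate <= 0) {
    stop("flow rate and acquisition resolution must be > 0", call. = FALSE)
  }
  structure(m, class = "instrument_model")
}

#' Fluorescence population model for synthetic event streams
#'
#' Describes the fluorescence clusters the generator draws from, per
#' staining mode. Under SYBR Green only (`SG`, total cell counts) all cells
#' appear in two clusters of low (LNA) and high (HNA) nucleic-acid content
#' separated on the green channel. Under SYBR Green + propidium iodide
#' (`SG+PI`, intact cell counts) membrane-damaged cells take up PI and shift
#' to high red (FL3) fluorescence, outside the intact gate. Distributions
#' are log10-normal per channel; location parameters are in log10 instrument
#' units (dex).
#'
#' The instrument prototype publishes no numeric cluster coordinates, so the
#' defaults are chosen to sit cleanly inside the shipped gates: LNA at
#' FL1 ~ 5e3, HNA at ~ 2e4 (boundary 1e4), intact FL3 ~ 160, PI-positive
#' FL3 ~ 6.3e3, background below the 1000 FL1 threshold.
#'
#' Mixing weights follow the tap/wastewater origin split of the reactor
#' trajectory: tap water carries 65 % LNA cells (71 % among intact cells),
#' wastewater 38.7 % LNA (61.3 % HNA).
#'
#' @param clusters Named list per staining mode (`SG`, `SG+PI`) of named
#'   subpopulation parameter lists with elements `fl1_mean`, `fl1_sd`,
#'   `fl3_mean`, `fl3_sd` (log10 units). Partial overrides are merged over
#'   the defaults.
#' @param pct_lna_tap_tcc,pct_lna_tap_icc Percent LNA among tap-water cells
#'   (all cells / intact cells).
#' @param pct_lna_wastewater Percent LNA among wastewater cells.
#' @param fl1_drift_rate Slow SG-channel FL1 cluster drift during chlorine
#'   exposure, dex per minute of exposure (cosmetic cluster shift emulating
#'   DNA-damage-reduced stain binding; count losses are modeled in the
#'   reactor kinetics, not here).
#' @return An object of class `population_model`.
#' @examples
#' population_model()$clusters$SG$lna
#' @export
population_model <- function(clusters = list(),
                             pct_lna_tap_tcc = 65,
                             pct_lna_tap_icc = 71,
                             pct_lna_wastewater = 38.7,
                             fl1_drift_rate = 0.005) {
  defaults <- list(
    "SG" = list(
      lna = list(fl1_mean = 3.7, fl1_sd = 0.1, fl3_mean = 2.2, fl3_sd = 0.15),
      hna = list(fl1_mean = 4.3, fl1_sd = 0.1, fl3_mean = 2.3, fl3_sd = 0.15),
      background = list(fl1_mean = 2.5, fl1_sd = 0.2,
                        fl3_mean = 1.6, fl3_sd = 0.2)
    ),
    "SG+PI" = list(
      lna = list(fl1_mean = 3.7, fl1_sd = 0.1, fl3_mean = 2.2, fl3_sd = 0.15),
      hna = list(fl1_mean = 4.3, fl1_sd = 0.1, fl3_mean = 2.3, fl3_sd = 0.15),
      damaged = list(fl1_mean = 3.5, fl1_sd = 0.2,
                     fl3_mean = 3.8, fl3_sd = 0.15),
      background = list(fl1_mean = 2.5, fl1_sd = 0.2,
                        fl3_mean = 1.6, fl3_sd = 0.2)
    )
  )
  for (mode in names(clusters)) {
    if (!mode %in% names(defaults)) {
      stop("unknown staining mode '", mode, "'", call. = FALSE)
    }
    for (pop in names(clusters[[mode]])) {
      if (!pop %in% names(defaults[[mode]])) {
        stop("unknown subpopulation '", pop, "' for mode ", mode,
             call. = FALSE)
      }
      defaults[[mode]][[pop]] <- utils::modifyList(defaults[[mode]][[pop]],
                                                   clusters[[mode]][[pop]])
    }
  }
  pcts <- c(pct_lna_tap_tcc = pct_lna_tap_tcc,
            pct_lna_tap_icc = pct_lna_tap_icc,
            pct_lna_wastewater = pct_lna_wastewater)
  if (any(pcts < 0 | pcts > 100)) {
    stop("percent-LNA parameters must be in [0, 100]", call. = FALSE)
  }
  if (fl1_drift_rate < 0) stop("fl1_drift_rate must be >= 0", call. = FALSE)
  for (mode in names(defaults)) {
    cl <- defaults[[mode]]
    if (cl$lna$fl1_mean >= cl$hna$fl1_mean) {
      stop("LNA median FL1 must lie below HNA median FL1", call. = FALSE)
    }
  }
  structure(list(clusters = defaults,
                 pct_lna_tap_tcc = pct_lna_tap_tcc,
                 pct_lna_tap_icc = pct_lna_tap_icc,
                 pct_lna_wastewater = pct_lna_wastewater,
                 fl1_drift_rate = fl1_drift_rate),
            class = "population_model")
}

#' Fixed gate definitions for event classification
#'
#' The fixed-gating strategy of the analysis chain: a lower FL1 threshold
#' separating instrument noise from cells, a bacterial gate (polygon in
#' (log10 FL1, log10 FL3) space), a vertical FL1 boundary splitting low
#' (below) from high (at/above) nucleic-acid content cells, and -- for the
#' SG+PI staining mode -- an intact gate excluding PI-positive
#' (membrane-damaged) events. Shipped defaults match the generator's default
#' clusters; real-instrument users override them.
#'
#' @param fl1_threshold Lower FL1 detection threshold, instrument units.
#' @param bacteria_gate Two-column matrix of polygon vertices in
#'   (log10 FL1, log10 FL3).
#' @param lna_hna_boundary FL1 value (instrument units) splitting LNA
#'   (below) from HNA (at or above).
#' @param intact_gate Polygon for the intact population under SG+PI; events
#'   outside it are treated as background (not intact cells).
#' @return An object of class `gate_set`.
#' @examples
#' gate_set()
#' @export
gate_set <- function(fl1_threshold = 1000,
                     bacteria_gate = default_bacteria_gate(),
                     lna_hna_boundary = 1e4,
                     intact_gate = default_bacteria_gate()) {
  bacteria_gate <- as.matrix(bacteria_gate)
  intact_gate <- as.matrix(intact_gate)
  for (poly in list(bacteria_gate, intact_gate)) {
    if (ncol(poly) != 2 || nrow(poly) < 3 || any(!is.finite(poly))) {
      stop("gate polygons need >= 3 finite (log10 fl1, log10 fl3) vertices",
           call. = FALSE)
    }
    if (polygon_self_intersects(poly)) {
      stop("gate polygon must be simple (non-self-intersecting)",
           call. = FALSE)
    }
  }
  if (fl1_threshold < 0) stop("fl1_threshold must be >= 0", call. = FALSE)
  lb <- log10(lna_hna_boundary)
  if (lb < min(bacteria_gate[, 1]) || lb > max(bacteria_gate[, 1])) {
    stop("lna_hna_boundary must lie within the bacteria gate FL1 extent",
         call. = FALSE)
  }
  structure(list(fl1_threshold = fl1_threshold,
                 bacteria_gate = bacteria_gate,
                 lna_hna_boundary = lna_hna_boundary,
                 intact_gate = intact_gate),
            class = "gate_set")
}

#' @rdname gate_set
#' @export
default_bacteria_gate <- function() {
  cbind(log10_fl1 = c(3.0, 5.5, 5.5, 3.0),
        log10_fl3 = c(1.3, 1.3, 3.2, 3.2))
}

# segment-intersection scan; shared endpoints between adjacent edges are fine
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  intersects <- function(p, q) {
    d1 <- cross(q[1, ], q[2, ], p[1, ]); d2 <- cross(q[1, ], q[2, ], p[2, ])
    d3 <- cross(p[1, ], p[2, ], q[1, ]); d4 <- cross(p[1, ], p[2, ], q[2, ])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (intersects(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

# even-odd (ray casting) point-in-polygon test, vectorized over points;
# points exactly on an edge may land on either side (gates are defined with
# clusters well away from edges)
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf(
    "Continuous FCM instrument: %g ul/min, %g ms windows, 1:%g stain dilution,\n",
    x$cytometer_flow_rate, x$acquisition_resolution_ms,
    x$staining_dilution_factor))
  cat(sprintf("  %g min staining delay, FL1 threshold %g, background %g ev/s\n",
              x$staining_delay_min, x$detection_threshold_fl1,
              x$background_event_rate))
  invisible(x)
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf("Gate set: FL1 threshold %g; LNA/HNA boundary %g;\n",
              x$fl1_threshold, x$lna_hna_boundary))
  cat(sprintf("  bacteria gate: %d-vertex polygon, log10 FL1 [%g, %g], log10 FL3 [%g, %g]\n",
              nrow(x$bacteria_gate),
              min(x$bacteria_gate[, 1]), max(x$bacteria_gate[, 1]),
              min(x$bacteria_gate[, 2]), max(x$bacteria_gate[, 2])))
  invisible(x)
}
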