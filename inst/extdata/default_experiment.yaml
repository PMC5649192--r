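# Benchmark experiment: 500 ml stirred reactor, four phases
# (baseline | wastewater contamination | shock-chlorination | washout).
# Values equal the package defaults; kept explicit for provenance.
experiment:
  initial_volume: 500        # ml
  tap_tcc: 130.6             # cells/ul
  tap_icc: 99.6
  contaminant_tcc: 14700     # 10-fold pre-diluted wastewater
  contaminant_icc: 9840      # implied by the intact-cell plateau
  contaminant_rate: 3        # ml/min
  contaminant_duration: 5    # min
  chlorine_stock: 72         # mg/l free chlorine
  chlorine_rate: 2.5         # ml/min
  chlorine_duration: 5       # min
  flowthrough_rate: 100      # ml/min -> dilution rate 0.2 /min
  phase_start_times: [0, 15, 30, 45]
  total_duration: 80
  time_step: 1
kinetics:
  icc_kill_rate: 0.8         # 1/min
  tcc_decay_rate: 10.6       # cells/ul/min, batch chlorination only
  chlorine_demand_rate: 0.03 # 1/min
  kill_threshold: 0.05       # mg/l (DPD detection limit)
instrument:
  cytometer_flow_rate: 14    # ul/min
  acquisition_resolution_ms: 100
  staining_dilution_factor: 2
  staining_delay_min: 10
  detection_threshold_fl1: 1000
  background_event_rate: 0.5 # events/s
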