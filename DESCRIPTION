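Package: rtfcm
Title: In-Silico Replay of a Drinking-Water Contamination and Shock-Chlorination
    Experiment Tracked by Continuous Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a laboratory-scale drinking-water reservoir (a stirred
    500 ml batch/flow-through reactor) through a four-phase contamination and
    shock-chlorination experiment, generates the raw event stream a continuous
    staining flow cytometer would record (SYBR Green and SYBR Green + propidium
    iodide channels, 100 ms acquisition resolution), and provides the gating,
    60 s binning, fingerprinting and kinetic-analysis chain that turns raw
    events into 1-min total (TCC) and intact (ICC) cell concentration time
    series. Includes perfect-mixing mass-balance predictions, first-order
    chlorine disinfection kinetics, onset detection, washout-rate fitting, and
    measured-versus-predicted comparison reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
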