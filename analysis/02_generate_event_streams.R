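#!/usr/bin/env Rscript
# Stage 2: synthetic instrument.
# Generates the continuous 100 ms event streams both staining channels
# would record over the 90-min acquisition (80 min experiment + 10 min
# staining delay), from the simulated trajectory of stage 1.

suppressPackageStartupMessages(library(rtfcm))
dir.create("results", showWarnings = FALSE)

seed <- 1
trajectory <- simulate_experiment(experiment_config(), kinetic_params())
inst <- instrument_model()
pops <- population_model()
acq_min <- 80 + inst$staining_delay_min

sg <- generate_event_stream(trajectory, inst, pops, "SG", acq_min,
                            seed = seed + 1)
sgpi <- generate_event_stream(trajectory, inst, pops, "SG+PI", acq_min,
                              seed = seed + 2)
write_event_stream(sg, "results/events_sg.csv")
write_event_stream(sgpi, "results/events_sgpi.csv")

cat(sprintf("SG stream    : %6d events over %d min (TCC channel)\n",
            nrow(sg$events), acq_min))
cat(sprintf("SG+PI stream : %6d events over %d min (ICC channel)\n",
            nrow(sgpi$events), acq_min))
cat(sprintf("expected tap-water rate: %.1f events/min at %.1f cells/ul\n",
            expected_events_per_window(130.6, inst, 60000), 130.6))
cat("wrote results/events_sg.csv, results/events_sgpi.csv (+ .meta.json)\n")
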