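#!/usr/bin/env Rscript
# Simulate the reference session: coupled LFP + dendritic fluorescence
# with known ground truth, written as a session container plus sidecar
# truth tables. Downstream scripts read results/session/.

library(swrdspike)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(duration = 300, lfp_rate = 10000, event_rate = 16,
                  n_dendrites = 2, dspike_prob = 0.9, seed = 20260920)
ses <- simulate_session(cfg)
write_session(ses, "results/session")
yaml::write_yaml(unclass(cfg), "results/sim_config.yaml")

ev <- ses$truth$events
cat(sprintf("Simulated %.0f s at %.0f kHz: %d SPW-R complexes (%d doublets, %.1f%%),\n",
            cfg$duration, cfg$lfp_rate / 1000, nrow(ev),
            sum(ev$kind == "doublet"), 100 * mean(ev$kind == "doublet")))
cat(sprintf("%d dendrites, %d scheduled dendritic spikes, %d global (bAP) events.\n",
            cfg$n_dendrites, sum(ses$truth$dspikes$dspike), nrow(ses$truth$baps)))
cat("Session written to results/session/\n")
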