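#!/usr/bin/env Rscript
# Match calcium responses to SPW-R complexes ([T3, Tpeak] x [T1, T2]
# overlap, nearest time zero), classify each response as a local
# dendritic spike or a global bAP from its spatial profile, and compute
# activation ratios.

library(swrdspike)

ses <- read_session("results/session")
images <- lapply(ses$dendrites, compute_dff)
resp <- as.data.frame(data.table::fread("results/ca_responses.csv"))
rip <- as.data.frame(data.table::fread("results/ripple_events.csv"))
rip <- rip[!rip$rejected, ]

matched <- match_events(resp, rip)
matched <- classify_responses(matched, images)
data.table::fwrite(matched[, c("response_id", "dendrite_id", "mode",
                               "matched_event_id", "jitter_ms", "slope",
                               "distal_proximal_ratio")],
                   "results/dendritic_events.csv")

ratios <- activation_ratios(matched, nrow(rip), length(images))
jit <- matched$jitter_ms[matched$mode == "local_dspike"]
cat(sprintf("%d of %d responses matched an SPW-R complex; modes: %d dSpikes, %d bAPs, %d unclassified.\n",
            sum(!is.na(matched$matched_event_id)), nrow(matched),
            sum(matched$mode == "local_dspike"),
            sum(matched$mode == "global_bap"),
            sum(matched$mode == "unclassified")))
cat(sprintf("Total activation ratio %.1f%% (%d dSpikes / %d SPW-Rs); active dendrites %d/%d.\n",
            100 * ratios$total_ratio, ratios$n_dspikes, ratios$n_ripples,
            ratios$n_active_dendrites, ratios$n_dendrites))
cat(sprintf("Ripple-peak to calcium-peak delay: %.1f +/- %.1f ms (mean +/- SD).\n",
            mean(jit, na.rm = TRUE), sd(jit, na.rm = TRUE)))
cat("Dendritic event table written to results/dendritic_events.csv\n")
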