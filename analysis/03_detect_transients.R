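#!/usr/bin/env Rscript
# Compute dF/F and detect dendritic calcium responses with the 2 SD rule
# (baseline SD from the first 100-500 ms; 60 ms peak window; T3/T4
# threshold crossings).

library(swrdspike)

ses <- read_session("results/session")
images <- lapply(ses$dendrites, compute_dff)
resp <- do.call(rbind, lapply(images, detect_responses))
resp$response_id <- seq_len(nrow(resp))
data.table::fwrite(resp, "results/ca_responses.csv")

cat(sprintf("Detected %d calcium responses across %d dendrites.\n",
            nrow(resp), length(images)))
cat(sprintf("Peak amplitudes: median %.2f dF/F (range %.2f-%.2f); median area %.2f dF/F*s.\n",
            median(resp$peak_amp_dff), min(resp$peak_amp_dff),
            max(resp$peak_amp_dff), median(resp$area_dffs)))
cat("Response table written to results/ca_responses.csv\n")
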