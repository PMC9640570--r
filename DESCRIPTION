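Package: swrdspike
Title: Sharp-Wave Ripple Coupled Dendritic Calcium Spike Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking hippocampal sharp-wave ripples (SPW-Rs)
    recorded in the local field potential to dendritic calcium spikes imaged in
    parvalbumin-positive interneurons. Implements ripple detection by
    difference-of-Gaussian band filtering with a 4 SD envelope threshold and
    300 ms complex merging, dF/F transient detection with a 2 SD rule,
    ripple-calcium coincidence matching, three-group event classification
    (low-ripple, high-ripple, doublet) by spectral-histogram decomposition,
    a nearest-neighbour gap statistic and two-step K-means, dendritic
    spatial-threshold and hot-spot/propagation analysis, and quantification of
    supralinear summation during SPW-R doublets. A phenomenological forward
    model generates coupled LFP and dendritic fluorescence with known ground
    truth so that every stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    mclust,
    minpack.lm,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
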