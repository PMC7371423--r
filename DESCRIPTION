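Package: photolearn
Title: Trial-Based Analysis of Fiber-Photometry Calcium Signals During
    Go/No-Go Discrimination Learning
Version: 0.1.0
Authors@R:
    person("Photolearn", "Developers", email = "photolearn@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for analysing trial-aligned fiber-photometry
    calcium signals recorded while animals learn a go/no-go auditory
    discrimination task. Provides d-prime learning curves with sigmoid
    psychometric fits and learning thresholds, per-trial dF/F
    normalisation, two-dimensional learning maps, time-resolved ROC/AUC
    discrimination between trial types with trial-shuffled null bands and
    discrimination latencies, response-curve versus learning-curve
    correlation, video motion-energy detection with movement-free signal
    truncation, the rank-based hypothesis tests used throughout, and a
    seeded synthetic-session generator with known ground truth so every
    stage is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
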