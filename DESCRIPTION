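Package: lfpstates
Title: Behavioral State Segmentation and State-Conditioned LFP Oscillation
    Analysis
Version: 0.1.0
Authors@R:
    person("Home Cage", "Electrophysiology Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised segmentation of home-cage behavioral states from two
    movement sensors (head-mounted accelerometer magnitude and pose-tracking
    nose speed) via median-threshold symbolization and a discrete-emission
    hidden Markov model (Baum-Welch estimation, Viterbi decoding, canonical
    state labeling), together with state-conditioned analyses of multichannel
    local field potentials: per-epoch band power (delta, gamma, high-gamma),
    directed interactions by conditional and spectral Granger causality from
    vector autoregressive models, and delta-phase to gamma-amplitude
    cross-frequency coupling.  Includes a synthetic-data generator with known
    latent states, sensor emissions, planted VAR coupling and planted
    phase-amplitude coupling so that every stage is testable without real
    recordings, bespoke statistics (Sarle bimodality coefficient, multi-sample
    circular median test), and a config-driven pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
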