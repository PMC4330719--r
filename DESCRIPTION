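Package: aepdecode
Title: Single-Trial Auditory Evoked Potential Decoding from Noisy EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for single-trial classification of auditory
    events (chirp vs. silence) from multichannel EEG recorded in high-artifact
    environments. Implements band-pass filtering, rule-based bad-channel
    rejection, artifact subspace reconstruction, extended-infomax independent
    component analysis with train-to-test weight transfer, Kalman filtering
    with an N100/P300 event-related potential state-space model, and
    least-squares probabilistic classification with nested cross-validation
    and permutation testing. Ships a synthetic EEG session generator with
    known ground truth (mixing matrices, per-trial evoked responses, planted
    bad channels and artifact regimes) so every stage is testable without
    access to real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
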