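Package: ictalwave
Title: Electrographic Seizure Detection, Phase-Amplitude Coupling and
    Wavelet Phase Coherence for Rodent EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based detection and onset classification (low-voltage
    fast, hypersynchronous, incremental) of spontaneous electrographic
    discharges in rodent EEG; complex Morlet continuous wavelet transform
    with phase and amplitude extraction; phase-amplitude coupling via the
    Kullback-Leibler modulation index on a log-spaced comodulogram grid
    with 4-s windows and peri-ictal epoch averaging; wavelet phase
    coherence between paired recording sites; in-vitro field potential
    event detectors (sharp waves, interictal spikes, ictal discharges);
    and a synthetic local-field-potential generator that plants discharges,
    cross-frequency coupling, phase-locked pairs, movement artifacts and
    slice events with known ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
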