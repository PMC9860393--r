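Package: gradespike
Title: Graded-Amplitude Calcium Spike and Dual-Peak Extracellular Action
    Potential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-analysis pipeline for neurons that fire graded-amplitude
    calcium spikes, such as cerebrospinal-fluid-contacting neurons.  Detects
    Ca2+ spikes on the conditioned derivative of delta-F/F fluorescence,
    quantifies dual-peak extracellular action potentials (EAPs) and their
    running integral, flags multimodal amplitude distributions with a
    Jarque-Bera statistic against Monte-Carlo critical values, and relates
    EAP integrals to Ca2+ spike amplitudes in paired recordings.  Includes a
    ground-truth synthetic-data generator (Poisson spike trains, log-normal
    amplitude mixtures, GCaMP6f-like transient kernels, three-lobe EAP
    templates, pharmacology and agonist transforms) so every stage is
    verifiable by recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
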