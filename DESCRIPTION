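Package: swdus
Title: Swarm Decomposition and Fetal Cardiac Valve Timing from Doppler Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes single-channel fetal Doppler ultrasound audio into
    oscillatory components with swarm filtering (a swarm-prey hunting model of
    band-selective filtering applied in a sifting-like loop), locates the four
    per-beat valve events (mitral closing, aortic opening, aortic closing,
    mitral opening) inside physiological search windows on the envelope of the
    valve-motion component, converts them to the cardiac time intervals ICT,
    VET, IRT, PEP and STI, and summarises cohorts by gestational-age group
    with nonparametric tests (Kruskal-Wallis, pairwise Mann-Whitney, Spearman
    age correlations). Includes a fully parameterised synthetic Doppler
    generator with ground-truth beat schedules and event times so that every
    pipeline stage is testable without recordings, plain-text CSV/WAV/YAML
    interfaces, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
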