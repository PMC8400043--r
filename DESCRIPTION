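Package: sonouroflow
Title: Acoustic Uroflowmetry: Psychoacoustic Features and LSTM Flowrate Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-invasive uroflowmetry from voiding sounds. Converts mono
    recordings of urination into psychoacoustic feature sequences (Zwicker-style
    loudness in sone and roughness in asper via short-time Fourier analysis,
    Bark-scale excitation patterns and masking depth), predicts the urinary
    flowrate curve from those features with a small sequence-to-sequence LSTM,
    computes standard uroflowmetry metrics (Qmax, Qavg, voided volume,
    interruptions) from flowrate or load-cell weight traces, and classifies
    bladder-emptying health into bell-shaped, staccato and interrupted patterns
    with a sequence-to-label LSTM. Includes a seeded generator of synthetic
    voiding events (flow archetypes, weight traces, paired sound features,
    calibration tones) so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
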