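Package: amdetect
Title: Behavioral and Neural Analysis of Amplitude-Modulation Depth Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking Go/Nogo amplitude-modulation (AM) depth-detection
    behavior to auditory-cortex single-unit and population coding. Provides
    signal-detection d-prime scoring with rate clipping, cumulative-Gaussian
    psychometric fitting with detection thresholds at d-prime = 1, per-unit
    neurometric functions (firing-rate d-prime, logistic fits, AM-responsivity
    classification, vector strength and the Rayleigh test), and a subsampled
    leave-one-out linear support-vector-machine population readout converted to
    d-prime. Includes a synthetic-data generator (Bernoulli observer over a
    cumulative-Gaussian psychometric function; inhomogeneous Poisson spike
    trains with sinusoidal 5 Hz rate modulation and tunable phase locking) so
    the full pipeline is testable end to end without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    e1071,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
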