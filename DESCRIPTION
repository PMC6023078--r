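Package: bpinterp
Title: Breathing-Pattern Interpretation for Acoustic Assistive Communication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for interpreting acoustically recorded, user-modulated
    breathing patterns as an augmentative and alternative communication
    (AAC) channel. Recordings are denoised with a single-channel Wiener
    filter driven by decision-directed a-priori SNR tracking, reduced to
    low-rate breath envelopes via sub-sampling, rectification and
    Butterworth low-pass filtering, and classified against a user-trained
    template library by 1-nearest-neighbour matching under Euclidean and
    dynamic time warping distances, emitting the phrase mapped to the
    winning class. A seeded generator of synthetic modulated breathing
    recordings reproduces the acquisition protocol (4 classes, 10 training
    and 5 live repetitions per class, temporally warped live sets) so the
    full pipeline can be exercised and evaluated without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
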