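Package: cricketsong
Title: Models of Resonant Song Recognition in Crickets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and fitting of candidate pulse-pattern recognition
    mechanisms for cricket acoustic communication. Implements rectangular
    pulse-train stimuli and two-dimensional pulse-pause preference fields
    (PPFs); four minimal recognition models (delay-line autocorrelation,
    post-inhibitory rebound with coincidence detection, rebound with
    feedforward inhibition, and a resonate-and-fire neuron); a five-neuron
    song-recognition network; a leaky integrate-and-fire neuron with
    adaptation (LIFAC) for isolating individual resonant peaks; multi-start
    Nelder-Mead model fitting with parameter recovery; song-waveform
    segmentation and carrier-frequency estimation; and a Monte-Carlo
    band-overlap analysis of song periods across a cricket genus.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
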