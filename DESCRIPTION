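Package: axodelay
Title: Spiking Neural Networks with Learnable Axonal Delays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Spike Response Model (SRM) networks with per-neuron
    learnable integer axonal delays, local skip-connections that compensate for
    information lost to the post-spike reset, and a spike-rate objective
    augmented with a suppressed-membrane penalty on wrong-class output neurons.
    Training uses surrogate-gradient backpropagation through time with a
    finite-difference gradient for the delays, which are clipped and rounded to
    integer steps after every optimizer update. Includes readers for
    event-based audio spike data (SHD-schema HDF5 and plain-text event lists),
    spike binning and padding utilities, a synthetic coincidence-coding task
    generator whose class identity is carried purely by inter-channel timing,
    named ablation configurations with exact parameter accounting, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
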