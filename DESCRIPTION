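Package: abidecode
Title: Decoders and Phantom Simulation for Acoustoelectric Brain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding acoustoelectric brain-imaging (ABI) signals.
    Implements the baseline envelope decoder (DAE, analytic-signal magnitude)
    and an adaptive Fourier-fitting decoder (aDAF) that expands the envelope
    into harmonics of the record fundamental by least squares and keeps the
    dominant low-frequency component.  Includes a seeded phantom simulator
    that emulates pulse-train (1 kHz PRF) recordings amplitude-modulated by
    low-frequency current sources, the standard preprocessing chain
    (decimation to 5 kHz, third-order band-pass around the PRF), scan-grid
    image reconstruction with interpolation, dB maps, SNR and -3 dB
    source-width metrics, and tidy comparison reports for the two decoders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
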