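Package: mycovolt
Title: Spectral Analysis of Extracellular Voltage Recordings from Fungal Mycelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting electrical activity of fungal mycelium in
    slow differential-electrode voltage recordings. Provides a documented
    plain-text recording format, missing-sample cleaning, zero-phase
    anti-alias filtering with rational resampling, short-time Fourier
    transform spectrograms with a four-term Blackman-Harris window,
    band-integrated power spectral density, pre/post-induction segment
    comparison by Welch's t-test with Shapiro-Wilk diagnostics and
    percent-change reporting, and a seeded generator of synthetic
    multichannel mycelial recordings for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    readr,
    ggplot2,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
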