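Package: dapsysr
Title: Read, Write, Convert and Verify DAPSYS-Style Binary
    Electrophysiology Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with the discontinuous-page binary recording
    format used by the DAPSYS neurophysiological data acquisition system, as
    encountered in microneurography. Provides a bit-exact reader and writer
    for a documented reference dialect of the format (fixed header, flat
    store of waveform and text data pages, hierarchical table of contents,
    version footer), navigation and assembly of per-stream data into tidy
    tibbles, conversion to a generic recording model (continuous traces,
    event series, sorted-spike series), export to NIX-structured HDF5 and to
    the fixed-precision DAPSYS CSV dialect, a rounding-aware verification
    comparator for checking binary reads against CSV exports, and a
    deterministic generator of synthetic microneurography-like sessions so
    every layer can be tested without access to real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
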