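Package: ntamatch
Title: In Silico Spectral Library Matching for Non-Targeted Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying unknown small molecules in non-targeted
    high-resolution mass spectrometry by matching experimental MS2 spectra
    against a library of in-silico predicted spectra. Reads Mascot Generic
    Format (MGF) spectra and NIST-style MSP libraries, retrieves candidate
    compounds by adduct-aware precursor mass within a ppm window (with
    optional molecular-formula filtering), scores candidates with a
    normalized dot product over a fragment mass window, aggregates scores
    across collision energies, normalizes to ranks, percentiles and
    quotients, and calibrates percentile/quotient cutoffs from ROC sweeps
    with true/false positive rate reporting per mixture. Includes a fully
    seeded synthetic-benchmark generator (compound databases with tunable
    isobar density, per-collision-energy predicted spectra, noise-corrupted
    experimental spectra, and truth tables) so the whole workflow is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
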