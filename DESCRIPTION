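Package: hydrolevels
Title: Hydropathy Water-Wave Profiles and Level-Set Synchronization Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sliding-window hydropathy profiling of protein sequences on the
    Moret-Zebende (2007) fractal solvent-accessible-surface-area scale and the
    classical Kyte-Doolittle (1982) scale, detection of hydrophobic peaks and
    hydrophilic valleys, and a level-set synchronization statistic: the mean
    deviation of the k highest hydrophobic peaks of the smoothed profile.
    Includes a window-width sweep to locate the family-optimal smoothing
    window, cross-species comparison tables, a power-law fitter for the
    segment-SASA exponent that defines Moret-Zebende-type scales, and a
    synthetic sequence generator that plants hydrophobic peaks with known
    level and spread for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
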