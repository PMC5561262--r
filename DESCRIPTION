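Package: ddplexr
Title: Multiplex Droplet Digital PCR Quantification and Method Validation
Version: 0.1.0
Authors@R:
    person("ddplexr", "developers", email = "ddplexr@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative multiplex droplet digital PCR (ddPCR)
    analysis of genetically modified (GM) material. Converts droplet
    partition counts into Poisson-corrected target concentrations and
    relative GM content, applies well-level quality control, and implements
    the ENGL-style method-validation battery: trueness (bias), repeatability
    and reproducibility (RSD), absolute and relative limits of detection and
    quantification from dilution series, dynamic-range linearity, and
    robustness comparisons. Includes an in-silico multiplex specificity
    screen (ungapped primer-dimer alignment scoring, exhaustive primer-pair
    combination enumeration, mismatch-tolerant in-silico PCR with probe
    cross-checking) and a synthetic droplet-data generator that reproduces
    the statistical structure of multiplex ddPCR experiments for testing
    the full pipeline without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
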