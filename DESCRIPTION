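Package: mprasim
Title: Synthetic Massively Parallel Reporter Assays from Thermodynamic
    Models of Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates RNA-Seq-based massively parallel reporter assays
    (MPRAs) from first principles. Promoter variant libraries are scored
    with sequence-specific thermodynamic (states-and-weights) models of
    transcription built from per-position energy matrices, with optional
    extensions for allosteric (MWC) induction, chemical-potential
    titration of binding-site copies, genome-wide non-specific polymerase
    binding, extrinsic copy-number noise, and non-equilibrium steady
    states of promoter kinetic graphs via the Matrix Tree Theorem. The
    resulting synthetic expression tables are summarised with the field's
    standard MPRA statistics: information footprints, expression-shift
    profiles and matrices, per-site average mutual information, and
    signal-to-noise ratios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
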