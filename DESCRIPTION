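Package: novopair
Title: Spectral-Library-Assisted De Novo Peptide Sequencing for Paired
    HCD/ETD Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo peptide sequencing from pairs of HCD and ETD tandem
    mass spectra of the same precursor. Annotated spectral libraries (NIST-style
    MSP) are used as training data to attach significance scores to two peak
    selection criteria (amino-acid mass difference and fragment-ion
    complementarity); a spectrum pair is merged into a single scored peak list,
    sequence tags are generated, extended and ranked, and a tag-anchored
    spectrum-graph search returns ranked full-length peptide candidates. A
    synthetic-spectrum module generates annotated libraries and spectrum pairs
    with known ground truth, so the whole pipeline is testable without external
    data.
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
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
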