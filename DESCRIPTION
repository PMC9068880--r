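Package: hcrprobes
Title: Design of HCR v3 Split-Initiator Probe Pairs for In Situ Hybridization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs order-ready split-initiator probe pairs for third
    generation hybridization chain reaction (HCR v3) fluorescent in situ
    hybridization. From a transcript sequence and its coding-sequence
    annotation, the pipeline enumerates 25-nt candidate windows, screens
    them with a nearest-neighbor melting-temperature model corrected for
    monovalent salt and formamide, removes candidates that map to multiple
    loci of a reference (built-in k-mer matcher or imported SAM
    alignments), pairs adjacent survivors with a 2-nt spacer, appends the
    amplifier's split-initiator arms, and selects up to 36 non-overlapping
    pairs preferring the open reading frame, then the 3' UTR, then the
    5' UTR. Includes a reproducible synthetic transcript/genome fixture
    generator, tabular (tibble) interfaces throughout, ggplot2 probe maps,
    and a command-line entry point.
License: MIT + file LICENSE
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
    Rsamtools,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
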