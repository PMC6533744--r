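Package: radsub
Title: Subtractive RAD-Seq Discovery of Sex-Specific Markers and Sex-Reversal Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering sex-specific (sex-limited) markers from
    double-digest RAD sequencing by presence/absence subtraction, and for
    applying those markers to call genetic sex and detect hormone- or
    temperature-induced sex reversal. Includes a synthetic ddRAD data
    generator (in-silico double digestion, size selection, barcoded
    paired-end read simulation with planted heterogametic-sex-limited
    regions), inline-barcode demultiplexing, read cleaning and fixed-length
    tag trimming, exact tag stacking into per-individual catalogs,
    cross-sex subtractive screening with an opposite-genome filter,
    in-silico PCR genotyping against a validated primer panel, and
    genetic-versus-phenotypic sex discordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
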