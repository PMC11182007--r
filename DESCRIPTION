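Package: thermoscan
Title: Descriptor-Driven Discovery and Validation of fourU RNA Thermometers
Version: 0.1.0
Authors@R:
    person("thermoscan", "maintainers", email = "maintainers@thermoscan.dev",
           role = c("aut", "cre"))
Description: A pipeline for discovering fourU-class RNA thermometers in
    genomic sequences. Parses text motif descriptors (ordered single-stranded
    and helical elements with per-position constraints, mismatch allowances
    and optional positions), scans FASTA genomes for descriptor occurrences
    with full base-pair complementarity constraints including G-U wobble,
    curates matches into ranked candidates using Shine-Dalgarno spacing,
    fourU-run and wobble-pair rules, verifies hairpin support with a weighted
    Nussinov fold, designs stabilizing U-to-C mutations at wobble positions,
    and quantifies reporter-assay heat induction in Miller units. Includes a
    synthetic-data generator (planted genomes, decoys, simulated assays) so
    every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
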