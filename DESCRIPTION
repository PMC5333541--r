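Package: conserved16s
Title: Conservation Analysis of 16S rRNA 'Conserved' Regions via
    Degenerate Primer Contigs and k-mer Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how conserved the so-called conserved regions of the
    bacterial 16S rRNA gene actually are. Published PCR primers targeting each
    conserved region are assembled into IUPAC-degenerate "primer contigs";
    every 12-mer window of each contig is expanded into its unambiguous
    isoforms and searched exactly against a sequence database (e.g. SILVA SSU
    Ref NR99). Contig-length fragments are then recovered from every database
    record by anchoring on the highest-frequency 12-mer, reduced to
    non-redundant sequences, and summarised as fractionally-weighted
    per-position nucleotide frequency matrices, conservation masks and IUPAC
    consensus strings. A seeded synthetic SILVA-like database generator with a
    ground-truth manifest makes every pipeline stage testable offline.
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
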