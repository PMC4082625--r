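Package: synrec
Title: Synteny Blocks, Evolutionary Breakpoints and Meiotic Recombination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects homologous synteny blocks (HSBs) and evolutionary
    breakpoint regions (EBRs) from tables of orthologous gene coordinates in
    two genomes, merges and filters breakpoint calls against telomeric and
    centromeric masks, and classifies the underlying rearrangements
    (inversions, fusions, fissions, indels, translocations) by type and size.
    Companion modules compute tandem-repeat and gene-density landscapes in
    100-Kbp windows, DAVID-style EASE-score functional annotation clustering
    around breakpoints and inside inversions, and chromosome-specific meiotic
    recombination statistics (MLH1 focus maps on synaptonemal complexes,
    crossover densities inside and outside inversions, centimorgan
    conversion). A synthetic-data generator produces rearranged genome pairs
    with known breakpoints, window landscapes, term annotations with planted
    enrichment, and simulated meiotic cells with obligate crossover,
    interference and configurable crossover suppression inside inversions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
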