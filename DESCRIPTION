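Package: teinv
Title: Transposable-Element Signatures at Chromosomal Inversion Breakpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising the role of transposable elements (TEs)
    in the origin of chromosomal inversions. Calls inversion breakpoint
    intervals from whole-genome alignments (PAF) and refines them with
    split-read evidence; computes sliding-window TE density tracks and
    breakpoint-versus-background enrichment tests with centromere exclusion;
    evaluates same-family TE co-occurrence in breakpoint pairs against a
    mock-region resampling null; detects terminal inverted repeats, tandem
    periodicity and consensus-coverage pileups in repeat consensus sequences;
    and classifies the likely inversion mechanism (ectopic recombination
    between TE copies versus non-homologous end joining) from breakpoint-region
    signatures. A seeded synthetic-genome generator producing ancestral/derived
    haplotype pairs with known breakpoints, mechanisms and truth alignments is
    included as the test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp,
    tools,
    IRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
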