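Package: nplikeness
Title: Natural-Product-Likeness Scoring of Small Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks small molecules by their similarity to the structure space
    of natural products. Molecules read from SDF (V2000) or SMILES files are
    curated (counter-ion removal, element whitelist, deglycosylation), every
    heavy atom is described by a canonical circular atom signature of
    configurable height, and fragment document frequencies from a
    natural-product corpus and a synthetic-molecule corpus are combined into
    a normalized log-ratio NP-likeness score per molecule. Includes a seeded
    generator of natural-product-like and synthetic-like test corpora,
    density plots of score distributions, and a command-line interface for
    curation, signature generation, training and scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
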