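Package: glunmap
Title: Residue Equivalence Maps and Annotation Transfer Across NMDA Receptor GluN Subunits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds residue-level equivalence maps between the GluN1, GluN2A
    and GluN2B subunits of the NMDA receptor from per-domain rigid-body
    structural superposition of alpha-carbon models, with sequence-alignment
    fallback for structurally unsolved regions. The maps are used to find
    homologous missense variants (same amino-acid change at structurally
    equivalent positions) and to transfer pathogenicity and
    loss-/gain-of-function annotations between subunits, and to evaluate
    annotation concordance across equivalent positions. Includes a
    deterministic synthetic-data generator (toy helix/sheet structure pairs
    and planted variant databases) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
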