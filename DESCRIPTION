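Package: prime3d2d
Title: Template-Based Protein-RNA Docking from Protein 3D and RNA Secondary Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-based modelling of protein-RNA complexes that couples
    protein tertiary-structure alignment with RNA secondary-structure
    alignment. Implements a structural-alphabet encoding of RNA secondary
    structure, a BLOSUM-style log-odds substitution matrix trained from
    gapless alignment blocks, a global affine-gap aligner over combined
    sequence and structure scores (RNA2dA), the combined 3D2D template
    ranking score (W * TM-score + (1 - W) * SSI), rigid-body model building
    by Kabsch superposition, binding-site transfer by alignment, and the
    associated evaluation statistics (ligand RMSD, interface RMSD, top-N
    success rate, phase-transition analysis, and binary classification
    metrics). Deterministic synthetic fixtures make the whole pipeline
    testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
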