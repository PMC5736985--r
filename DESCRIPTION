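Package: pepscreen
Title: Gene-Family Expansion Screening and Peptidase Sequence/Structure Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative screening of peptidase gene families across
    arthropod genomes. Implements a three-criterion expansion screen (exact
    Mann-Whitney U by full enumeration over midranks, tie-corrected
    Kruskal-Wallis, and a strict percentile-90 flag with linear interpolation
    between closest ranks), largest monospecific-clade fractions on
    phylogenetic trees, a genomic-neighborhood classifier separating genuine
    horizontal gene transfer from assembly contamination, alignment-column
    Shannon entropy and N-glycosylation sequon scanning, archetype-based
    substrate-subsite profiling of A1 aspartic peptidases, and a deterministic
    Shrake-Rupley solvent-accessible surface area engine with exposed
    basic-residue counting. Ships seeded synthetic-data generators with
    planted ground truth for every input kind, and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    bio3d,
    Biostrings,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
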