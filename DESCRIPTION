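Package: npdesign
Title: Natural-Product-Inspired Reaction-Driven De Novo Molecular Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline toolkit for forward-synthetic de novo design of
    natural-product-inspired small molecules. Candidate molecules are grown
    from purchasable building blocks through virtual reaction schemes
    (substructure-mapped transforms) under a deterministic breadth-first
    search bounded at three linear synthesis steps, ranked against a template
    by CATS topological pharmacophore correlation-vector distance, summarised
    by Bemis-Murcko scaffold statistics, and annotated with putative
    macromolecular targets by a cascade of two self-organizing maps over
    complementary descriptor spaces with empirical p-values. Includes a
    minimal molecular core (SMILES parsing, canonicalization, aromaticity
    perception, exact monoisotopic masses, SD file input/output) and seeded
    synthetic-fixture generators so every stage runs and is tested without
    network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
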