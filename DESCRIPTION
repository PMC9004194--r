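Package: tedensity
Title: Windowed Transposable-Element Density Around Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the proportion of base pairs occupied by transposable
    elements (TEs) in sliding windows upstream, intragenically, and downstream
    of every gene in a genome. Overlapping TEs are first merged within matching
    order and superfamily groupings (plus an all-TE total grouping) so that
    densities stay bounded in [0, 1]; densities are then computed per
    pseudomolecule as a 4-D tensor over (identity, window, gene, direction)
    and persisted in HDF5 stores. Includes strand-aware upstream/downstream
    reporting, per-gene top-N summary tables, percentile gene lists, density
    binning against companion values such as expression, and paired syntelog
    density differences between genomes. A synthetic-genome generator and an
    independent per-base occupancy-mask oracle make the whole pipeline
    testable without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    parallel,
    purrr,
    readr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
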