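Package: bsascan
Title: Bulked Segregant Analysis by SNP-Index Genome Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Next-generation-sequencing bulked segregant analysis (BSA) for
    quantitative trait locus discovery in backcross populations. Covers raw-read
    quality control with per-cycle diagnostics, per-sample variant summaries
    (transition/transversion ratios, zygosity, indel length spectra, impact-class
    tallies), trait statistics and rule-based construction of phenotypic extreme
    bulks, per-site SNP-index and delta-SNP-index computation, sliding-window
    genome scans with simulation-based significance thresholds, and candidate
    region calling. Ships a synthetic BC2F2 data generator (recombinant
    populations, correlated seedling traits with a planted QTL, bulk read depths,
    and defective reads) so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    MASS,
    dplyr,
    tidyr,
    tibble,
    rlang,
    Biostrings,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
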