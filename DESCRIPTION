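Package: paleomito
Title: Authentication and Geographic Clade Assignment of Ancient Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale museomics pipeline for degraded (ancient and
    historic museum) specimens: quality trimming of short reads, seeded
    mapping to small circular mitochondrial references with best-reference
    selection, coordinate-based duplicate removal, terminal deamination
    (damage) profiling, minimum-depth consensus calling with coverage QC,
    clade-diagnostic-site discovery with per-site read agreement statistics
    for contamination assessment, diagnostic-site clade assignment, and
    median-joining haplotype networks. A built-in ancient-DNA read simulator
    with complete ground truth (terminal C-to-T / G-to-A damage, sequencing
    error, PCR duplicates, contaminant admixture) drives every stage at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    rlang,
    S4Vectors,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
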