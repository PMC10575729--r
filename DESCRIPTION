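Package: m6amSeq
Title: Single-Base Identification of Cap-Adjacent m6Am Sites from
    Antibody-Enrichment Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of m6Am-Seq experiments for single-base
    identification of cap-adjacent N6,2'-O-dimethyladenosine (m6Am). Provides
    a truth-annotated four-library read simulator (input, m7G-IP, FTO- m6A-IP,
    FTO+ m6A-IP), per-transcript coverage and read-start tracks, sliding-window
    IP-enrichment peak calling with FTO-sensitivity and cap-proximity filters,
    per-nucleotide m6Am scoring from the read-start rate (m1) and the FTO
    demethylation contrast (m2), position-frequency-matrix consensus motifs,
    Ribo-Seq translation-efficiency ratios, and replicate/assay gene-set
    integration, orchestrated by a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
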