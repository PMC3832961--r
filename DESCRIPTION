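Package: panelforge
Title: Degenerate Primer Panel Design and Amplicon Classification for
    Gene Families
Version: 0.1.0
Authors@R:
    person("Panelforge", "Developers", email = "panelforge@example.org",
           role = c("aut", "cre"))
Description: Tools for building suites of degenerate PCR primers that
    tile a gene family, and for analysing the amplicons such suites
    recover.  A gene-family phylogeny is partitioned into primer-design
    groups by branch length or percent nucleotide identity; per-group
    IUPAC consensus primers are screened against nearest-neighbor
    thermodynamic constraints (melting-temperature window, hairpin
    stability, primer-dimer free energy); panels are validated by
    in-silico PCR with perfect-match and mismatch-tolerant modes; and
    recovered amplicon contigs are trimmed, translated, classified into
    primer groups, screened for chimeras, clustered into >=90 percent
    amino-acid-identity ortholog types, binned by novelty, and tabulated
    across samples.  A seeded synthetic gene-family generator makes the
    whole workflow testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
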