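Package: mgotu
Title: Marker Gene-Based Operational Taxonomic Units for Metagenomic
    Profiling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and extends databases of species-level, marker gene-based
    operational taxonomic units (mOTUs) from universal single-copy marker
    genes, profiles metagenomic inserts against them with an explicit
    "unassigned" fraction, and evaluates the resulting profiles.  Includes
    greedy centroid clustering with per-family identity cutoffs, a k-mer
    seeded read profiler with rarefaction and Shannon diversity, MinHash
    sketch distances and V-measure clustering congruence, CAMI/OPAL-style
    profile quality metrics (F1, L1 norm error, completeness, purity,
    weighted UniFrac error over the taxonomy, sum-of-ranks), and a
    Wilcoxon + generalized fold change differential abundance workflow.
    Synthetic-data generators with controlled sequence identity structure
    make every component testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
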