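Package: plastomics
Title: Comparative Plastome Genomics: Quadripartite Structure, Codon Usage,
    Microsatellites and IR Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid (chloroplast)
    genomes. Reads and writes GenBank flat files with a normalized gene
    feature model; detects the quadripartite structure (LSC, IRb, SSC, IRa)
    of a circular plastome from sequence self-complementarity alone; computes
    base composition, GC content and AT/GC skew statistics for genomes,
    regions and codon positions; counts codons and computes relative
    synonymous codon usage (RSCU), amino acid frequencies, start codon
    inventories and cross-taxon significantly variable codons (SVCs); scans
    for perfect microsatellites (SSRs) under MISA-style repeat thresholds
    with one inverted repeat copy removed; characterizes gene content at the
    four IR junctions, including extensions into the repeats and gene
    overlaps; summarizes tables of predicted C-to-U RNA editing sites; and
    prepares concatenated supermatrices of shared protein-coding genes from
    externally aligned per-gene files. A synthetic plastome generator with a
    full ground-truth sidecar makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
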