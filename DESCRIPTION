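Package: moscreen
Title: Morpholino Off-Target Screening and Knockdown Readout Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for antisense morpholino oligonucleotide design review in
    zebrafish knockdown studies. Implements a five-rule decision tree for
    off-target candidate screening (named-gene filter, binding-orientation
    filter, translation- versus splice-blocking site classification, and a
    duplex melting-temperature cut-off), a nearest-neighbor melting
    temperature model for morpholino:RNA duplexes, affine-gap global pairwise
    alignment with stretcher-style identity/similarity/gap percentages for
    human-zebrafish ortholog comparison, and the quantitative readouts of a
    knockdown experiment: ordinal phenotype score tabulation, maximum
    fluorescence intensity extraction, one-way ANOVA with Tukey multiple
    comparisons, and delta-delta-Ct knockdown efficiency. A seedable
    synthetic-data module generates toy genomes with annotated gene models,
    planted binding sites of every decision-tree class with ground-truth
    labels, and synthetic readout tables, so the whole pipeline can be
    exercised end-to-end without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
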