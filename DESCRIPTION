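Package: dachroma
Title: Differential Chromatin Accessibility Domains from Single-Copy FISH
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of differential accessibility (DA) between metaphase
    chromosome homologs measured by single-copy FISH probes. Quantifies
    per-homolog hybridization signal in metaphase images with gradient
    vector flow (GVF) active contours and the normalized homolog intensity
    ratio |I1-I2|/(I1+I2); scores categorical cell-level intensity calls
    into DA/EA classifications with the accompanying statistical battery
    (binomial normal approximation, two-proportion z, Mann-Whitney U,
    Kruskal-Wallis, Welch t); designs single-copy probe intervals under
    repeat-divergence, copy-number-variant and expression constraints with
    nearest-neighbor primer thermodynamics; aggregates concordant DA probes
    into genomic domains with span/gap/target-length reporting; integrates
    open-chromatin signal tracks over intervals; and classifies domain
    overlap with topologically associated domains (TADs). Ships synthetic
    generators (images, score tables, repeat landscapes, signal tracks,
    TAD partitions) with known ground truth so the full pipeline is
    testable without external data, plus the published probe coordinate
    table as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    pracma,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
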