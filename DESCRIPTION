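Package: chromtrace
Title: Chromatin Tracing by Sequential DNA-FISH: Probe Design, Trace
    Reconstruction and Distance Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for allele-specific chromatin tracing of a
    contiguous genomic domain by multiplexed sequential DNA-FISH. Covers
    probe-panel design (fixed-length tiling of a target region, repeat-filtered
    30-nt targeting sequences, 130-nt template and 60-nt adapter oligo
    assembly, a round-by-channel readout codebook), a synthetic Gaussian-chain
    polymer and imaging simulator (localization noise, per-round drift,
    chromatic offset, detection dropout, nonspecific foci), registration
    (chromatic and drift correction, nucleus masking, 3D foci fitting), trace
    linking with missing-locus refitting, median spatial-distance matrices and
    log2 fold-change maps between conditions, and concordance of imaged
    distances with binned chromatin contact frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
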