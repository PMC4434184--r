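Package: nucelastic
Title: Sequence-Dependent Nucleosome Occupancy from DNA Bending Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts nucleosome occupancy from DNA sequence with an elastic
    forced-bending model of the nucleosomal superhelix: dinucleotide-step
    roll/tilt force constants and equilibrium angles give a deformation
    energy for every candidate dyad placement, which a Boltzmann weight and
    a sliding-window average convert into per-base-pair occupancy.
    Includes cubic-spline upsampling of coarse experimental occupancy
    tracks, strand-aware metaprofile aggregation around feature start/end
    anchors, per-family Spearman correlation of occupancy against GC
    content, identity and divergence, and a fully seeded synthetic-data
    generator (genomes, pseudogene-like features with nucleosome-inhibitory
    elements, mutated gene families, noisy coarse tracks) so the whole
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
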