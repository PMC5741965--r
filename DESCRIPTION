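Package: hvrscan
Title: Segmentation of Inbred Genomes into High-Variability Regions and
    Conservation-Guided Prioritisation of Haplotype Blocks
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segments a query genome into High and Low Variability Regions
    (HVR/LVR) from triangular-smoothed densities of strain-specific variants
    (SSVs) in 10 kb windows, ranks HVRs by cross-species conservation of
    transcription-factor occupancy (the CE score), and tests enrichment of
    genomic elements in HVR subsets with cluster-preserving permutation tests
    and Fisher's exact tests. Includes a synthetic mosaic-genome generator so
    the whole pipeline is testable without external data: planted haplotype
    blocks with bimodal per-window variant density, shared blocks between
    query and control strains, TF peaks with tunable conservation, unmappable
    stretches, expression with a planted differentially-expressed set, and a
    disease map with a planted enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
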