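Package: nucleodomain
Title: Mapping Nucleolus-Associated Domains from Nucleolar-DamID and
    rDNA-Anchored Hi-C
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping nucleolus-associated domains (NADs) from
    Nucleolar-DamID read counts and for extracting ribosomal-DNA-anchored
    contacts from Hi-C pairs mapped to an rDNA-appended reference. Builds
    GATC fragment maps, computes normalized log2 m6A ratio tracks, calls
    NAD domains by quantile thresholding with a permutation false-discovery
    rate, balances contact matrices by Knight-Ruiz scaling, derives A/B
    compartment eigenvectors and compartment-switch categories, partitions
    the genome into NAD-only / NAD-LAD / LAD-only / iNAD-iLAD repressive
    layers with relocation-fate analysis, and computes boundary
    metaprofiles and RPKM expression classes. A synthetic-data module
    plants known domain architecture so every stage is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Epigenetics, HiC, Sequencing, PeakDetection, Coverage
RoxygenNote: 7.3.3
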