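Package: enuscan
Title: Homozygosity Mapping and Variant Prioritization for Inbred ENU Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for forward-genetic ENU mutagenesis screens run
    on an inbred background, where the induced point mutations themselves
    serve as mapping markers. Filters putative ENU single-nucleotide variants
    against dbSNP-like, strain, pedigree and repeat exclusion sets; maps
    recessive causal loci by sliding-window homozygosity statistics
    (homozygous count, homozygous percentage and average novel allele
    frequency); partitions phenotypically mixed cohorts that map to more than
    one locus; extracts coding and splice-proximal candidate variants;
    screens for dominant modifiers of variably expressive phenotypes; and
    detects non-ENU deletions from soft-clipped read clusters. A forward
    simulator of the G2 backcross breeding design (founder mutation load,
    Haldane recombination, read sampling and genotype calling) provides
    ground-truth fixtures so every stage is verifiable without real mouse
    whole-genome sequencing data.
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
    SummarizedExperiment,
    VariantAnnotation,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
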