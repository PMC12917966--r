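Package: cpKin
Title: Chloroplast SNP Calling and Haplotype-Based Kinship Analysis for
    Conifer Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing intraspecific chloroplast genome variation
    and verifying pedigrees in paternally inheriting conifers such as
    loblolly pine (Pinus taeda). Implements a homoplasmy-aware chloroplast
    SNP caller over SAM alignments (mapping-quality, base-quality, depth and
    homoplasmy filters), assembly of per-sample calls into a samples-by-loci
    genotype matrix with a missing-data-as-reference policy, minor-allele
    frequency and carrier filters, gene/intergenic locus annotation,
    haplotype-distance parentage classification (paternal match, maternal
    leakage, alternate father, pollen contamination), exact binomial leakage
    tests and Poisson de novo mutation expectations, neighbor-joining trees
    with column-bootstrap support, and a synthetic-pedigree simulator that
    generates reference genomes, parental haplotypes, crosses with
    configurable contamination and leakage, and aligned short reads so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
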