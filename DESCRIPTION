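Package: kseed
Title: Reference-Free k-mer GWAS and Small RNA Evidence for Seed
    Pigmentation Loci
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reference-free, k-mer-based association pipeline for
    dissecting seed-pigmentation loci in inbred plant cohorts, modelled on
    the soybean I locus. Canonical 31-mer sets are counted per accession
    from whole-genome resequencing reads, singleton-filtered, assembled
    into a presence/absence matrix, encoded as a pseudo-VCF, and tested
    for case/control association with an allelic chi-squared statistic
    under Bonferroni control. Significant k-mers are anchored by exact
    match against reference sequences so that unanchored k-mers flag
    structural-variant junctions, and k-mer-derived genotypes are scored
    for concordance against reference-based calls. Companion RNA-evidence
    tools quantify splice-junction-spanning mRNA reads and partition
    small RNA mappings between exons and introns, the signature of a
    mirtron emitted from a chimeric subtilisin-chalcone synthase gene. A
    synthetic-data module generates cohorts, haplotypes and reads with
    the statistical structure of a biallelic recombinant locus so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: GenomeWideAssociation, StructuralVariation, SmallRNA,
    Sequencing, SNP
Config/testthat/edition: 3
RoxygenNote: 7.3.3
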