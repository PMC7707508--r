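# kseed

Reference-free, k-mer-based GWAS for seed-pigmentation loci, with the
RNA-evidence analyses that support a mirtron-triggered silencing model
of chalcone synthase (CHS) genes.

## Who this is for

Reference-based GWAS is blind to trait-associated sequence that the
reference assembly lacks. At loci like the soybean *I* locus — an
inverted-repeat CHS cluster whose recombinant allele (a truncated
subtilisin gene fused upstream of an inverted CHS1/CHS3 pair)
restricts pigment to the hilum — the causal structure is exactly such
missing sequence. kseed is for analysts who want to genotype
accessions by the presence/absence of canonical 31-mers in raw reads,
associate k-mers with binarized phenotypes, and read *failure to
anchor* a significant k-mer on the reference as evidence of a
structural breakpoint.

## The method

Per accession, canonical 31-mers (lexicographic minimum of a k-mer
and its reverse complement) are counted from reads and singletons are
discarded. The per-sample k-mer sets form a binary presence matrix,
filtered to presence frequencies in [0.05, 0.95] and encodable as a
pseudo-VCF (one biallelic record per k-mer, genotypes 0/0 and 1/1).
For a case/control bipartition of a color trait, every k-mer's 2×2
table (a, b, c, d) is tested with Pearson's allelic chi-squared,
1 df, no continuity correction:

    chi2 = n (ad − bc)² / [(a+b)(c+d)(a+c)(b+d)]

with Bonferroni control alpha/m over the m retained k-mers (a fixed
threshold such as 5e−9 can be supplied instead). Significant k-mers
are partitioned by exact-match lookup into anchored (with reference
positions) and unanchored (structural-variant candidates).
K-mer-derived SNP genotypes (ref/alt k-mer presence at each site) are
scored for concordance against reference-based calls. RNA-evidence
tools count splice-junction-spanning mRNA reads (minimum coverage 5)
and partition exact-mapped small RNAs between exons and introns — a
high intronic fraction confined to the chimeric gene is the mirtron
signature, and perfect-match coverage between paralogs bounds what
its products could target elsewhere.

A synthetic-data module generates the whole study — locus pair with a
known junction, inbred cohort with linked hilum phenotype, WGR/mRNA/
small-RNA reads — so the pipeline is testable end to end without
downloads. See `vignettes/kseed-methods.Rmd` for the model,
parameters and design choices.

## Worked example

```r
library(kseed)
truth  <- buildLocusPair(locusBlueprint(seed = 1))
cohort <- simulateCohort(cohortSpec(seed = 1), truth)
sets   <- cohortKmerSets(truth, cohort, readSimParams(seed = 1))
mat    <- buildPresenceMatrix(sets)
gw     <- runKmerGwas(mat, binarizeTrait(traitTable(cohort),
                                         "hilum", "colorless"))
gw
#> GwasResult | 4213 tests | alpha = 0.05 | threshold = 1.19e-05 | 1592 significant
#> Binarization | hilum : colorless ( 16 cases ) vs black+brown ( 44 controls )
#> top records:
#>                              kmer a  b  c d     chi2            p   fisher_p  odds_ratio significant
#> 1 AAAAAAGTGCTAGAGCGACCTGCGCATAGGT 0 16 43 1 55.18717 1.095819e-13 1.1363e-13 0.001044932        TRUE
#> 2 AAAAAATCGTCTTGTGTATTTCCCGGATCAG 0 16 43 1 55.18717 1.095819e-13 1.1363e-13 0.001044932        TRUE
#> 3 AAAAACGTTCCCAGACAGACCTAGAGGAAGC 0 16 43 1 55.18717 1.095819e-13 1.1363e-13 0.001044932        TRUE

idx <- buildReferenceIndex(c(ancestral = ancestralSeq(truth)),
                           name = "ancestral")
cls <- classifySignificantKmers(gw, idx)
nrow(cls$unanchored)                      # 30
all(cls$unanchored$kmer %in% junctionKmers(truth))  # TRUE
```

Reading: 16 of 60 accessions carry the recombinant allele and show
the colorless hilum; thousands of k-mers from the allele's structural
difference are Bonferroni-significant, but exactly the 30
junction-spanning 31-mers — present in carriers, absent from the
ancestral haplotype — fail to anchor on the ancestral reference.
Those 30 unanchored k-mers localize the recombination breakpoint that
reference-based analysis cannot see.

A command-line front end over the same functions is provided at
`inst/exec/kseed.R` (subcommands `simulate`, `count`, `kmer2vcf`,
`assoc`, `anchor`, `junctions`, `srna`).

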