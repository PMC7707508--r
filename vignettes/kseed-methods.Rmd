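---
title: "Reference-free k-mer association and the mirtron signature: methods"
author: "kseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free k-mer association and the mirtron signature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kseed)
```

# The problem

Reference-based GWAS calls variants against an assembly and therefore
cannot see trait-associated sequence that the assembly lacks. At the
soybean *I* locus — a cluster of inverted-repeat chalcone synthase
(CHS) genes controlling seed-coat and hilum pigmentation — exactly
this failure mode occurs: the recombinant allele restricting pigment
to the hilum involves a structural rearrangement (a truncated
subtilisin gene fused upstream of an inverted CHS1/CHS3 pair) that is
missing from reference assemblies. kseed implements the complementary
reference-free route: genotype accessions by the *presence or absence
of canonical 31-mers* in their raw reads, associate k-mers with
binarized color phenotypes by an allelic chi-squared test, and use
*failure to anchor* a significant k-mer on the reference as the
signal of a structural breakpoint. Companion tools quantify the RNA
evidence for the downstream silencing model: splice-junction-spanning
mRNA reads from the chimeric gene, and the partition of small-RNA
mappings between exons and introns that distinguishes a
mirtron-derived small-RNA population (intronic) from phasiRNAs
amplified off mature mRNAs (exonic).

# The statistical core

For accession $s$, let $K_s$ be the set of canonical 31-mers occurring
at least twice in its reads (singletons are discarded as likely
sequencing errors; a canonical k-mer is the lexicographic minimum of a
k-mer and its reverse complement under $A<C<G<T$). Over the cohort,
the union of the $K_s$ forms the rows of a binary presence matrix;
rows with presence frequency outside $[f, 1-f]$ (default $f = 0.05$)
are removed, the presence/absence analogue of a MAF filter. For a
case/control bipartition of a color phenotype, each k-mer yields a
2×2 table $(a, b, c, d)$ — cases with/without, controls with/without —
tested by Pearson's chi-squared with 1 df and no continuity
correction:

$$\chi^2 = \frac{n(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$

with $\chi^2 = 0,\ p = 1$ when a margin is degenerate. Significance is
controlled family-wise by Bonferroni, $p \le \alpha/m$ over the $m$
retained k-mers, with an optional fixed override (at genome scale,
$\alpha = 0.05$ over $10^7$ tests gives the conventional plotted
cutoff of $5\times10^{-9}$). Fisher's exact $p$ is reported alongside
whenever an expected cell is below 5, but ranking always uses the
chi-squared $p$, for parity with the standard allelic case/control
test. Ties in $p$ are broken lexicographically by k-mer, so results
are deterministic.

Presence is coded once per accession (a dominant 2×2), not
allele-doubled: presence of a k-mer in a read set carries no diploid
dosage information. No kinship or structure correction is applied in
the k-mer arm (the pseudo-VCF header carries a note to that effect);
mixed-model association is out of scope.

# Anchoring and concordance

Significant k-mers are localized by *exact* 31-mer lookup against one
or more reference indexes; BLAST-style inexact search is deliberately
not used, because the downstream inference ("this k-mer does not exist
in the assembly") rests precisely on exact occurrence. Significant
k-mers found in no reference are the structural-variant candidates.

To validate k-mer genotyping against reference-based calls, each
biallelic SNP site defines up to $k$ ref-allele and $k$ alt-allele
canonical k-mers (the k-windows overlapping the site); a sample
containing only ref k-mers is called ref/ref, only alt alt/alt, both
het, neither missing. Sites whose k-window overlaps another variant
are skipped as ambiguous. Concordance is the percentage of
non-missing genotype pairs that agree; zero comparable pairs is an
error rather than 0%. Het calling from presence of both allele k-mers
extends pure presence/absence genotyping so the comparison is
well-defined for heterozygous material; with the default (fully
inbred) synthetic cohort all truth genotypes are homozygous.

# RNA evidence

Small-RNA reads are adapter-called by a k-mer heuristic: the most
frequent probe-length window absent from the reference (a genomic
k-mer cannot be the adapter), required in ≥20% of reads and extended
greedily rightward while support holds; the detected adapter's leading
8-mer is the cut site, and trimmed reads outside 14–43 nt are
discarded. Mapping is exact-occurrence on both strands with all
multi-hits reported — hairpin-arm ambiguity (one read matching both
CHS1' and CHS3') is part of the phenomenon, so assigning multi-mappers
would destroy the signal. Per gene, a read fully inside an intron is
intronic, fully inside an exon exonic, and straddling reads are
excluded from the intronic fraction so the fraction reflects only
unambiguous attributions. Depth is accumulated per read-base over the
gene span.

Junction support for the chimeric transcript counts reads exactly
matching the concatenation of ≥8 bp of donor-exon suffix and ≥8 bp of
acceptor-exon prefix, against a supplied candidate junction set (the
annotated exon boundaries); de-novo spliced alignment is out of
scope. A junction passes at the conventional minimum coverage of 5.
Perfect-match coverage between paralogs reports the fraction of a
subject sequence covered by maximal exact shared substrings ≥20 bp in
either orientation — the ceiling on what a ≥20-nt small-RNA population
from one paralog could target in another by perfect complementarity.

# What the synthetic data emulates

`locusBlueprint()`/`buildLocusPair()` generate an ancestral haplotype
(intact subtilisin; CHS1, CHS3 = reverse complement of CHS1 mutated to
99.5% identity, CHS4 and CHS7 as paralogs with conserved exons but
independent random introns; random flanks and spacers; ~50 kb by
default) and a recombinant haplotype constructed as
`ancestral[0,p) ++ ancestral[q,n)`: the prefix ends at subtilisin
exon 4 and the suffix begins just upstream of CHS1. Because the
recombinant re-uses ancestral sequence everywhere except across the
single seam, the canonical k-mer difference (recombinant minus
ancestral) is *exactly* the 30 junction-spanning 31-mers — the
property the anchoring analysis detects. The suffix start is chosen
so that both seam-flanking bases differ from their ancestral
continuations (otherwise a window overhanging the seam by one or two
bases can coincide with ancestral sequence), and the builder asserts
the property at build time. The chimeric gene is annotated as
subtilisin exons 1–4 plus a terminal exon in downstream intergenic
sequence, so its new intron contains the CHS1'/CHS3' inverted pair —
the candidate mirtron precursor.

`simulateCohort()` draws homozygous locus alleles i.i.d. (default
frequency 0.3 in a cohort of 60 — large enough carrier counts for a
desk-scale power analysis), links the "colorless" hilum category to
the recombinant allele with penetrance 0.95 and phenocopy leak 0.013
(the leak mirrors the 1.3% presence of the junction k-mer in the
contrasting colored-hilum subpopulation), and plants ~40 SNPs in the
shared flanks (>2k bp from any structural boundary, >k bp apart) with
genotypes independent of phenotype. The default inbreeding
coefficient is F = 1 — accessions are pure selfing lines — so all SNP
genotypes are homozygous; at 15× coverage a heterozygous allele can
drop below the 2-count filter and be miscalled, so residual
heterozygosity (settable via `inbreeding`) trades realism for exact
err = 0 concordance.

Reads are uniform-start, random-strand, with i.i.d. substitution
errors (default 1%) and constant placeholder qualities ("I"); nothing
downstream uses qualities. Default depth is 15×, a realistic
resequencing depth for a diversity panel. mRNA reads are drawn from
the spliced chimeric transcript; small-RNA inserts are drawn 85% from
21–24 nt (the expected mature-size mode) and 15% uniformly from the
rest of 14–43 nt, primary reads from the hairpin arms and secondary
reads from paralog exons only, each with the 3' adapter appended.
One integer seed fans out to fixed per-stage streams, so every output
is reproducible from a single number.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: indels and CNVs, quality-score
and error-profile structure, GC and coverage bias, paired-end insert
variability beyond fixed spacing, population structure and kinship
(the association arm is uncorrected, so confounding in real cohorts
is untested), linkage disequilibrium beyond the single locus, and RNA
degradation or expression-level variation.

# Numerical and design choices

* k defaults to 31 and must lie in [3, 32]: the counter packs k-mers
  two bits per base into one 64-bit word (numeric order on packed
  words equals lexicographic order on the strings).
* Windows containing any non-ACGT symbol are skipped whole, matching
  common counter semantics; the singleton filter is applied per
  sample, before pooling, since the sequencing-error argument is
  per-library.
* Counting is an in-memory hash; external-memory partitioning is out
  of scope at the package's problem sizes.
* The presence-frequency band is closed: frequency exactly $f$ is
  retained.
* The pseudo-VCF encoding (contig "KMERS", POS = row rank, ID = k-mer,
  REF/ALT = A/T, genotypes 0/0 and 1/1) is a declared convention
  validated by round-trip through a standards-compliant parser; the
  original in-house encoding is undocumented, and association results
  do not depend on the choice.
* Locus spans round half away from zero to integer kbp.
* Odds ratios use a 0.5 continuity substitute in all cells when any
  cell is zero.
* Depth profiles count read-bases per position (the alternative,
  reads per position, differs only by a factor of read length for
  contained reads).
* Problem sizes in the test-suite and acceptance runs: a ~50 kb locus,
  60 accessions at 15×, 2,500 null k-mers over 120 accessions, 4,000
  small-RNA reads — sizes at which every property is checkable
  against brute-force oracles while the full pipeline completes in
  minutes.

# Known limitations

Exact-match mapping means one sequencing error unmaps a read, so
junction-read counts at 1% error are roughly a third of their
error-free expectation (still far above the coverage bar at the
default transcript depth). Adapter detection assumes a single
dominant 3' adapter; heterogeneous adapter mixes return the dominant
one or none. The anchoring index stores every position of every
canonical k-mer and is intended for locus- to BAC-scale references,
not whole genomes. The binarization enumerator is exponential in the
number of categories by construction (2^(c−1) − 1 bipartitions), as
intended for the small category counts of color traits.

# A worked run

```{r, eval = FALSE}
truth  <- buildLocusPair(locusBlueprint(seed = 1))
cohort <- simulateCohort(cohortSpec(seed = 1), truth)
sets   <- cohortKmerSets(truth, cohort, readSimParams(seed = 1))
mat    <- buildPresenceMatrix(sets)
gw     <- runKmerGwas(mat, binarizeTrait(traitTable(cohort),
                                         "hilum", "colorless"))
idx    <- buildReferenceIndex(c(ancestral = ancestralSeq(truth)),
                              name = "ancestral")
classifySignificantKmers(gw, idx)$unanchored
```

The unanchored table contains exactly the 30 junction-spanning
31-mers, first at every rank — the synthetic reenactment of finding a
structural breakpoint k-mer that no reference can place.
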