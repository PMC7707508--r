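## Central S4 data containers. Coordinates are 0-based half-open
## internally; emitted VCF/GFF3 are 1-based per their format specs.

#' KmerCountTable: canonical k-mer occurrence counts for one sample
#'
#' Holds the raw canonical k-mer counts of a single accession's reads,
#' before singleton filtering. Keys are canonical (lexicographic minimum
#' of a k-mer and its reverse complement under A<C<G<T).
#'
#' @slot sampleId Sample label.
#' @slot k K-mer length.
#' @slot counts Named integer vector, names canonical k-mers, all >= 1.
#' @exportClass KmerCountTable
setClass("KmerCountTable",
    representation(sampleId = "character", k = "integer",
                   counts = "integer"))

setValidity("KmerCountTable", function(object) {
    msg <- character()
    if (length(object@counts)) {
        if (any(object@counts < 1L)) msg <- c(msg, "all counts must be >= 1")
        nm <- names(object@counts)
        if (is.null(nm)) return("counts must be named by k-mer")
        if (any(nchar(nm) != object@k))
            msg <- c(msg, "all keys must have length k")
    }
    if (length(msg)) msg else TRUE
})

#' SampleKmerSet: a sample's canonical k-mers after min-count filtering
#'
#' The unit of reference-free genotyping: the set of canonical k-mers an
#' accession's reads support at or above the minimum count (default 2,
#' dropping singletons as likely sequencing errors).
#'
#' @slot sampleId Sample label.
#' @slot k K-mer length.
#' @slot kmers Sorted character vector of canonical k-mers.
#' @slot nRaw Total k-mer instances counted before filtering.
#' @exportClass SampleKmerSet
setClass("SampleKmerSet",
    representation(sampleId = "character", k = "integer",
                   kmers = "character", nRaw = "numeric"))

setValidity("SampleKmerSet", function(object) {
    if (length(object@kmers) && any(nchar(object@kmers) != object@k))
        return("all k-mers must have length k")
    if (is.unsorted(object@kmers)) return("k-mers must be sorted")
    TRUE
})

#' PresenceMatrix: k-mer x sample presence/absence genotypes
#'
#' Binary matrix over the union of per-sample k-mer sets, restricted to
#' k-mers whose presence frequency lies inside the polymorphism band
#' [minFreq, 1 - minFreq]. Rows are lexicographically ordered k-mers.
#'
#' @slot kmers Ordered canonical k-mer row keys.
#' @slot sampleIds Column labels.
#' @slot presence Logical matrix, k-mers x samples.
#' @slot freq Per-k-mer presence frequency.
#' @slot k K-mer length.
#' @slot minFreq The frequency filter bound applied.
#' @exportClass PresenceMatrix
setClass("PresenceMatrix",
    representation(kmers = "character", sampleIds = "character",
                   presence = "matrix", freq = "numeric", k = "integer",
                   minFreq = "numeric"))

setValidity("PresenceMatrix", function(object) {
    msg <- character()
    d <- dim(object@presence)
    if (d[1] != length(object@kmers) || d[2] != length(object@sampleIds))
        msg <- c(msg, "presence dimensions must match kmers x sampleIds")
    if (anyDuplicated(object@kmers)) msg <- c(msg, "duplicate k-mer rows")
    if (length(object@freq) != length(object@kmers))
        msg <- c(msg, "freq length must match rows")
    if (length(msg)) msg else TRUE
})

#' Binarization: one case/control bipartition of trait categories
#'
#' @slot trait Trait name the bipartition is over.
#' @slot caseCategories,controlCategories Disjoint category sets.
#' @slot caseSamples,controlSamples Disjoint, nonempty sample lists;
#'   samples with missing labels are excluded from both.
#' @exportClass Binarization
setClass("Binarization",
    representation(trait = "character",
                   caseCategories = "character",
                   controlCategories = "character",
                   caseSamples = "character",
                   controlSamples = "character"))

setValidity("Binarization", function(object) {
    msg <- character()
    if (length(intersect(object@caseCategories, object@controlCategories)))
        msg <- c(msg, "case/control categories must be disjoint")
    if (length(intersect(object@caseSamples, object@controlSamples)))
        msg <- c(msg, "case/control samples must be disjoint")
    if (!length(object@caseSamples) || !length(object@controlSamples))
        msg <- c(msg, "case and control sample sets must be nonempty")
    if (length(msg)) msg else TRUE
})

#' GwasResult: per-k-mer case/control association results
#'
#' Records are sorted by ascending p, ties broken by k-mer lexicographic
#' order. The significance threshold is Bonferroni alpha/mTests unless a
#' fixed override was supplied.
#'
#' @slot records data.frame with columns kmer, a, b, c, d, chi2, p,
#'   fisher_p, odds_ratio, significant.
#' @slot binarization The Binarization tested.
#' @slot mTests Number of tests (retained k-mer rows).
#' @slot alpha Family-wise error rate.
#' @slot threshold Significance cutoff on p.
#' @exportClass GwasResult
setClass("GwasResult",
    representation(records = "data.frame", binarization = "Binarization",
                   mTests = "integer", alpha = "numeric",
                   threshold = "numeric"))

setValidity("GwasResult", function(object) {
    r <- object@records
    need <- c("kmer", "a", "b", "c", "d", "chi2", "p", "fisher_p",
              "odds_ratio", "significant")
    if (!all(need %in% names(r))) return("records missing columns")
    if (nrow(r) && is.unsorted(r$p)) return("records must be sorted by p")
    TRUE
})

#' LocusBlueprint: parameters of the synthetic recombinant locus
#'
#' Describes a pigmentation locus where a truncated subtilisin gene is
#' fused upstream of an inverted CHS1'/CHS3' chalcone-synthase pair: the
#' structure of the recombinant (colorless-hilum) haplotype versus the
#' ancestral arrangement.
#'
#' @slot flankLen Flank length either side of the gene region, bp.
#' @slot subtilisinExons Exon lengths of the intact subtilisin (>= 4).
#' @slot subtilisinIntronLen Intron length between subtilisin exons.
#' @slot chsGeneLen CHS paralog length, bp.
#' @slot chsIntronStart,chsIntronLen The single CHS intron, as 0-based
#'   offset within the gene and length.
#' @slot chs13Identity CHS1'/CHS3' arm identity, in (0.95, 1].
#' @slot novelExonLen Length of the chimeric gene's terminal exon.
#' @slot spacerLen Intergenic spacer length, bp.
#' @slot seed RNG seed for sequence generation.
#' @exportClass LocusBlueprint
setClass("LocusBlueprint",
    representation(flankLen = "integer", subtilisinExons = "integer",
                   subtilisinIntronLen = "integer", chsGeneLen = "integer",
                   chsIntronStart = "integer", chsIntronLen = "integer",
                   chs13Identity = "numeric", novelExonLen = "integer",
                   spacerLen = "integer", seed = "integer"))

setValidity("LocusBlueprint", function(object) {
    msg <- character()
    lens <- c(object@flankLen, object@subtilisinExons,
              object@subtilisinIntronLen, object@chsGeneLen,
              object@chsIntronLen, object@novelExonLen, object@spacerLen)
    if (any(lens <= 0L)) msg <- c(msg, "all lengths must be > 0")
    if (length(object@subtilisinExons) < 4L)
        msg <- c(msg, "subtilisin needs >= 4 exons")
    if (object@chs13Identity <= 0.95 || object@chs13Identity > 1)
        msg <- c(msg, "chs13Identity must be in (0.95, 1]")
    if (object@chsIntronStart < 1L ||
        object@chsIntronStart + object@chsIntronLen >= object@chsGeneLen)
        msg <- c(msg, "CHS intron must fit strictly inside the gene")
    if (length(msg)) msg else TRUE
})

#' LocusTruth: ground truth for a synthetic ancestral/recombinant pair
#'
#' @slot ancestralSeq,recombinantSeq Haplotype sequences.
#' @slot junctionPos 0-based offset of the recombination junction on the
#'   recombinant sequence (first base of the fused suffix).
#' @slot geneModels data.frame of exons: gene_id, contig
#'   ("ancestral"/"recombinant"), strand, exon start/end (0-based
#'   half-open), ordered within gene.
#' @slot snpSites data.frame: pos (0-based, on ancestralSeq), ref, alt.
#' @slot chimericJunctions data.frame: donor_end, acceptor_start (0-based
#'   half-open exon boundaries of the chimeric transcript on the
#'   recombinant sequence).
#' @slot regions data.frame of named features (contig, name, start, end,
#'   0-based half-open), e.g. CHS1/CHS3 arms of the chimeric intron.
#' @slot k K-mer length the junction-privacy guarantee was checked at.
#' @exportClass LocusTruth
setClass("LocusTruth",
    representation(ancestralSeq = "character", recombinantSeq = "character",
                   junctionPos = "integer", geneModels = "data.frame",
                   snpSites = "data.frame", chimericJunctions = "data.frame",
                   regions = "data.frame", k = "integer"))

setValidity("LocusTruth", function(object) {
    msg <- character()
    gm <- object@geneModels
    if (nrow(gm)) {
        for (g in unique(gm$gene_id)) {
            e <- gm[gm$gene_id == g, ]
            if (is.unsorted(e$start, strictly = TRUE) ||
                any(e$start[-1] < e$end[-nrow(e)]))
                msg <- c(msg, paste0("exons of ", g,
                                     " must be disjoint and sorted"))
        }
    }
    if (object@junctionPos < 0L ||
        object@junctionPos >= nchar(object@recombinantSeq))
        msg <- c(msg, "junctionPos out of range")
    if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of a synthetic accession cohort
#'
#' @slot nAccessions Number of accessions (>= 2).
#' @slot recombAlleleFreq Frequency of the recombinant haplotype.
#' @slot penetrance P(colorless hilum | recombinant allele).
#' @slot leak P(colorless hilum | ancestral allele).
#' @slot categories Named list of category labels per trait
#'   (seed_coat, hilum, pubescence), each >= 2 labels.
#' @slot inbreeding Inbreeding coefficient F for planted-SNP genotypes
#'   (selfing accessions: hets rare).
#' @slot seed RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(nAccessions = "integer", recombAlleleFreq = "numeric",
                   penetrance = "numeric", leak = "numeric",
                   categories = "list", inbreeding = "numeric",
                   seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    pr <- c(object@recombAlleleFreq, object@penetrance, object@leak,
            object@inbreeding)
    if (any(pr < 0) || any(pr > 1))
        msg <- c(msg, "all probabilities must be in [0, 1]")
    if (object@nAccessions < 2L) msg <- c(msg, "need >= 2 accessions")
    if (any(vapply(object@categories, length, 1L) < 2L))
        msg <- c(msg, "each trait needs >= 2 categories")
    if (length(msg)) msg else TRUE
})

#' Cohort: simulated accessions with alleles, traits and SNP genotypes
#'
#' @slot sampleIds Accession labels.
#' @slot alleles "ancestral" or "recombinant" per accession (homozygous;
#'   accessions are inbred).
#' @slot traits data.frame: accession_id, seed_coat, hilum, pubescence.
#' @slot snpGenotypes Character matrix sites x samples of "0/0", "0/1",
#'   "1/1" at the planted SNP sites.
#' @exportClass Cohort
setClass("Cohort",
    representation(sampleIds = "character", alleles = "character",
                   traits = "data.frame", snpGenotypes = "matrix"))

setValidity("Cohort", function(object) {
    msg <- character()
    if (length(object@alleles) != length(object@sampleIds))
        msg <- c(msg, "one allele per sample required")
    if (!all(object@alleles %in% c("ancestral", "recombinant")))
        msg <- c(msg, "alleles must be 'ancestral' or 'recombinant'")
    if (ncol(object@snpGenotypes) &&
        ncol(object@snpGenotypes) != length(object@sampleIds))
        msg <- c(msg, "snpGenotypes columns must match samples")
    if (length(msg)) msg else TRUE
})

#' ReferenceKmerIndex: exact-match index of a reference's canonical k-mers
#'
#' Maps every canonical k-mer of every contig to its occurrence
#' positions; the exact-match surrogate for BLAST localization of
#' significant k-mers.
#'
#' @slot name Reference label.
#' @slot k K-mer length.
#' @slot table data.table keyed by kmer: kmer, contig, offset (0-based),
#'   strand ("+" if the forward slice equals the canonical form).
#' @exportClass ReferenceKmerIndex
setClass("ReferenceKmerIndex",
    representation(name = "character", k = "integer", table = "ANY"))

#' GeneModel: exon structure of one gene on one contig
#'
#' Introns are derived as the gaps between consecutive exons.
#'
#' @slot geneId Gene label.
#' @slot contig Contig name.
#' @slot strand "+" or "-".
#' @slot exons IRanges of exons, 1-based closed (IRanges convention),
#'   sorted and disjoint.
#' @exportClass GeneModel
setClass("GeneModel",
    representation(geneId = "character", contig = "character",
                   strand = "character", exons = "ANY"))

setValidity("GeneModel", function(object) {
    e <- object@exons
    if (!is(e, "IRanges")) return("exons must be an IRanges")
    if (length(e) > 1) {
        s <- IRanges::start(e); en <- IRanges::end(e)
        if (is.unsorted(s, strictly = TRUE) || any(s[-1] <= en[-length(en)]))
            return("exons must be sorted and disjoint")
    }
    if (!object@strand %in% c("+", "-")) return("strand must be + or -")
    TRUE
})

#' SmallRnaProfile: small-RNA depth and exon/intron partition for a gene
#'
#' @slot geneId Gene label.
#' @slot depth Per-position read-base depth over the gene span.
#' @slot exonReads,intronReads,straddleReads Read counts by placement;
#'   straddling reads are excluded from the intronic fraction.
#' @slot intronicFraction intronReads / (exonReads + intronReads).
#' @exportClass SmallRnaProfile
setClass("SmallRnaProfile",
    representation(geneId = "character", depth = "numeric",
                   exonReads = "integer", intronReads = "integer",
                   straddleReads = "integer", intronicFraction = "numeric"))

setValidity("SmallRnaProfile", function(object) {
    f <- object@intronicFraction
    if (!is.na(f) && (f < 0 || f > 1))
        return("intronicFraction must be in [0, 1]")
    TRUE
})

#' ConcordanceReport: k-mer vs reference-call genotype concordance
#'
#' @slot nSites Sites compared.
#' @slot nGenotypes Non-missing genotype pairs compared.
#' @slot nMatching Matching pairs.
#' @slot percent 100 * nMatching / nGenotypes.
#' @slot perSite data.frame breakdown: site, compared, matching.
#' @exportClass ConcordanceReport
setClass("ConcordanceReport",
    representation(nSites = "integer", nGenotypes = "integer",
                   nMatching = "integer", percent = "numeric",
                   perSite = "data.frame"))

#' AdapterCall: detected small-RNA adapter
#'
#' @slot adapter Detected adapter sequence ("" if not found).
#' @slot support Reads containing it.
#' @slot fraction Fraction of reads containing it.
#' @slot found Whether a candidate cleared the support threshold.
#' @exportClass AdapterCall
setClass("AdapterCall",
    representation(adapter = "character", support = "integer",
                   fraction = "numeric", found = "logical"))

#' ParalogMatchReport: perfect-match coverage between two paralogs
#'
#' Fraction of the subject sequence covered by maximal exact shared
#' substrings of at least minLen bp (either orientation), the measure of
#' how much of a paralog a primary small-RNA population could target by
#' perfect complementarity.
#'
#' @slot queryGene,subjectGene Labels.
#' @slot minLen Minimum exact-match length, bp.
#' @slot coveredBp Covered bases of the subject.
#' @slot fraction coveredBp / subject length.
#' @slot intervals IRanges of merged covered intervals on the subject
#'   (1-based).
#' @exportClass ParalogMatchReport
setClass("ParalogMatchReport",
    representation(queryGene = "character", subjectGene = "character",
                   minLen = "integer", coveredBp = "integer",
                   fraction = "numeric", intervals = "ANY"))
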