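#' @name kseed-accessors
#' @title Accessors for kseed classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with `@`.
#' @param object A kseed S4 object.
NULL

#' @rdname kseed-accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname kseed-accessors
#' @export
setGeneric("kmerLength", function(object) standardGeneric("kmerLength"))
#' @rdname kseed-accessors
#' @export
setGeneric("kmers", function(object) standardGeneric("kmers"))
#' @rdname kseed-accessors
#' @export
setGeneric("kmerCounts", function(object) standardGeneric("kmerCounts"))
#' @rdname kseed-accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname kseed-accessors
#' @export
setGeneric("presence", function(object) standardGeneric("presence"))
#' @rdname kseed-accessors
#' @export
setGeneric("presenceFreq", function(object) standardGeneric("presenceFreq"))
#' @rdname kseed-accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname kseed-accessors
#' @export
setGeneric("significanceThreshold",
           function(object) standardGeneric("significanceThreshold"))
#' @rdname kseed-accessors
#' @export
setGeneric("ancestralSeq", function(object) standardGeneric("ancestralSeq"))
#' @rdname kseed-accessors
#' @export
setGeneric("recombinantSeq",
           function(object) standardGeneric("recombinantSeq"))
#' @rdname kseed-accessors
#' @export
setGeneric("junctionPos", function(object) standardGeneric("junctionPos"))
#' @rdname kseed-accessors
#' @export
setGeneric("geneModels", function(object) standardGeneric("geneModels"))
#' @rdname kseed-accessors
#' @export
setGeneric("snpSites", function(object) standardGeneric("snpSites"))
#' @rdname kseed-accessors
#' @export
setGeneric("chimericJunctions",
           function(object) standardGeneric("chimericJunctions"))
#' @rdname kseed-accessors
#' @export
setGeneric("locusRegions", function(object) standardGeneric("locusRegions"))
#' @rdname kseed-accessors
#' @export
setGeneric("alleles", function(object) standardGeneric("alleles"))
#' @rdname kseed-accessors
#' @export
setGeneric("traitTable", function(object) standardGeneric("traitTable"))
#' @rdname kseed-accessors
#' @export
setGeneric("snpGenotypes", function(object) standardGeneric("snpGenotypes"))
#' @rdname kseed-accessors
#' @export
setGeneric("exons", function(object) standardGeneric("exons"))
#' @rdname kseed-accessors
#' @export
setGeneric("introns", function(object) standardGeneric("introns"))
#' @rdname kseed-accessors
#' @export
setGeneric("intronicFraction",
           function(object) standardGeneric("intronicFraction"))

setMethod("sampleId", "KmerCountTable", function(object) object@sampleId)
setMethod("sampleId", "SampleKmerSet", function(object) object@sampleId)
setMethod("kmerLength", "KmerCountTable", function(object) object@k)
setMethod("kmerLength", "SampleKmerSet", function(object) object@k)
setMethod("kmerLength", "PresenceMatrix", function(object) object@k)
setMethod("kmerLength", "ReferenceKmerIndex", function(object) object@k)
setMethod("kmers", "SampleKmerSet", function(object) object@kmers)
setMethod("kmers", "PresenceMatrix", function(object) object@kmers)
setMethod("kmerCounts", "KmerCountTable", function(object) object@counts)
setMethod("sampleIds", "PresenceMatrix", function(object) object@sampleIds)
setMethod("sampleIds", "Cohort", function(object) object@sampleIds)
setMethod("presence", "PresenceMatrix", function(object) object@presence)
setMethod("presenceFreq", "PresenceMatrix", function(object) object@freq)
setMethod("records", "GwasResult", function(object) object@records)
setMethod("significanceThreshold", "GwasResult",
          function(object) object@threshold)
setMethod("ancestralSeq", "LocusTruth", function(object) object@ancestralSeq)
setMethod("recombinantSeq", "LocusTruth",
          function(object) object@recombinantSeq)
setMethod("junctionPos", "LocusTruth", function(object) object@junctionPos)
setMethod("geneModels", "LocusTruth", function(object) object@geneModels)
setMethod("snpSites", "LocusTruth", function(object) object@snpSites)
setMethod("chimericJunctions", "LocusTruth",
          function(object) object@chimericJunctions)
setMethod("locusRegions", "LocusTruth", function(object) object@regions)
setMethod("alleles", "Cohort", function(object) object@alleles)
setMethod("traitTable", "Cohort", function(object) object@traits)
setMethod("snpGenotypes", "Cohort", function(object) object@snpGenotypes)
setMethod("exons", "GeneModel", function(object) object@exons)
setMethod("introns", "GeneModel", function(object) {
    e <- object@exons
    if (length(e) < 2) return(IRanges::IRanges())
    IRanges::IRanges(start = IRanges::end(e)[-length(e)] + 1L,
                     end = IRanges::start(e)[-1] - 1L)
})
setMethod("intronicFraction", "SmallRnaProfile",
          function(object) object@intronicFraction)

setMethod("length", "SampleKmerSet", function(x) length(x@kmers))
setMethod("dim", "PresenceMatrix", function(x) dim(x@presence))

setMethod("show", "KmerCountTable", function(object) {
    cat("KmerCountTable | sample:", object@sampleId,
        "| k =", object@k,
        "|", length(object@counts), "distinct k-mers,",
        sum(object@counts), "instances\n")
})

setMethod("show", "SampleKmerSet", function(object) {
    cat("SampleKmerSet | sample:", object@sampleId,
        "| k =", object@k,
        "|", length(object@kmers), "k-mers (filtered) of",
        object@nRaw, "raw instances\n")
})

setMethod("show", "PresenceMatrix", function(object) {
    cat("PresenceMatrix |", length(object@kmers), "k-mers x",
        length(object@sampleIds), "samples | k =", object@k,
        "| freq band [", object@minFreq, ",", 1 - object@minFreq, "]\n")
})

setMethod("show", "Binarization", function(object) {
    cat("Binarization |", object@trait, ":",
        paste(object@caseCategories, collapse = "+"), "(",
        length(object@caseSamples), "cases ) vs",
        paste(object@controlCategories, collapse = "+"), "(",
        length(object@controlSamples), "controls )\n")
})

setMethod("show", "GwasResult", function(object) {
    cat("GwasResult |", object@mTests, "tests | alpha =", object@alpha,
        "| threshold =", format(object@threshold, digits = 3),
        "|", sum(object@records$significant), "significant\n")
    show(object@binarization)
    if (nrow(object@records)) {
        cat("top records:\n")
        print(head(object@records, 3))
    }
})

setMethod("show", "LocusTruth", function(object) {
    cat("LocusTruth | ancestral", nchar(object@ancestralSeq),
        "bp | recombinant", nchar(object@recombinantSeq),
        "bp | junction at", object@junctionPos,
        "|", nrow(object@snpSites), "planted SNPs |",
        length(unique(object@geneModels$gene_id)), "genes\n")
})

setMethod("show", "Cohort", function(object) {
    cat("Cohort |", length(object@sampleIds), "accessions |",
        sum(object@alleles == "recombinant"), "recombinant-allele |",
        nrow(object@snpGenotypes), "SNP sites\n")
})

setMethod("show", "ReferenceKmerIndex", function(object) {
    cat("ReferenceKmerIndex |", object@name, "| k =", object@k,
        "|", length(unique(object@table$kmer)), "distinct k-mers at",
        nrow(object@table), "positions\n")
})

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel |", object@geneId, "on", object@contig, object@strand,
        "|", length(object@exons), "exons,",
        max(0L, length(object@exons) - 1L), "introns\n")
})

setMethod("show", "SmallRnaProfile", function(object) {
    cat("SmallRnaProfile |", object@geneId, "| exonic:",
        object@exonReads, "intronic:", object@intronReads,
        "straddling:", object@straddleReads,
        "| intronic fraction:", round(object@intronicFraction, 4), "\n")
})

setMethod("show", "ConcordanceReport", function(object) {
    cat("ConcordanceReport |", object@nSites, "sites |",
        object@nMatching, "/", object@nGenotypes, "genotypes match |",
        round(object@percent, 2), "%\n")
})

setMethod("show", "AdapterCall", function(object) {
    if (object@found)
        cat("AdapterCall |", object@adapter, "| support", object@support,
            "(", round(100 * object@fraction, 1), "% of reads )\n")
    else cat("AdapterCall | adapter not found\n")
})

setMethod("show", "ParalogMatchReport", function(object) {
    cat("ParalogMatchReport |", object@queryGene, "->", object@subjectGene,
        "| >=", object@minLen, "bp perfect matches cover",
        object@coveredBp, "bp (",
        round(100 * object@fraction, 2), "% )\n")
})
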