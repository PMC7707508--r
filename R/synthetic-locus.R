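#' Blueprint for the synthetic recombinant pigmentation locus
#'
#' Parameterizes a locus pair modelled on the soybean I locus: an
#' ancestral haplotype carrying an intact subtilisin gene and a
#' chalcone-synthase (CHS) cluster with an inverted CHS1/CHS3 pair, and
#' a recombinant haplotype in which the 5' portion of the subtilisin
#' (exons 1-4) is fused upstream of the inverted CHS1'/CHS3' pair, which
#' then sits inside a new intron of the chimeric gene, followed by a
#' novel terminal exon.
#'
#' Defaults give an ancestral haplotype of about 50 kb.
#'
#' @param flankLen Flank length either side, bp.
#' @param subtilisinExons Exon lengths of the intact subtilisin gene
#'   (at least 4; exons beyond the 4th are lost in the recombinant).
#' @param subtilisinIntronLen Subtilisin intron length, bp.
#' @param chsGeneLen CHS paralog length, bp.
#' @param chsIntron Length-2 vector: 0-based start offset and length of
#'   the single CHS intron within a CHS gene.
#' @param chs13Identity Sequence identity between CHS1' and the reverse
#'   complement of CHS3', in (0.95, 1]; defaults above 0.99 (hairpin
#'   arms of the candidate mirtron must pair).
#' @param novelExonLen Length of the chimeric gene's terminal exon, bp.
#' @param spacerLen Intergenic spacer length, bp.
#' @param seed Integer seed; sequence generation is deterministic in it.
#' @return A [LocusBlueprint-class].
#' @export
locusBlueprint <- function(flankLen = 18000L,
                           subtilisinExons = c(350L, 220L, 260L, 240L, 300L),
                           subtilisinIntronLen = 180L,
                           chsGeneLen = 1800L,
                           chsIntron = c(600L, 600L),
                           chs13Identity = 0.995,
                           novelExonLen = 250L,
                           spacerLen = 1200L,
                           seed = 1234L) {
    new("LocusBlueprint",
        flankLen = as.integer(flankLen),
        subtilisinExons = as.integer(subtilisinExons),
        subtilisinIntronLen = as.integer(subtilisinIntronLen),
        chsGeneLen = as.integer(chsGeneLen),
        chsIntronStart = as.integer(chsIntron[1]),
        chsIntronLen = as.integer(chsIntron[2]),
        chs13Identity = chs13Identity,
        novelExonLen = as.integer(novelExonLen),
        spacerLen = as.integer(spacerLen),
        seed = as.integer(seed))
}

## Exon rows for one CHS-structured gene at absolute offset `at`
## (0-based); forward strand unless revcomp = TRUE, in which case exon
## coordinates are mirrored within the gene.
chsExonRows <- function(gene, contig, at, geneLen, intronStart, intronLen,
                        revcomp = FALSE) {
    e <- rbind(c(0L, intronStart),
               c(intronStart + intronLen, geneLen))
    if (revcomp) {
        e <- cbind(geneLen - e[, 2], geneLen - e[, 1])
        e <- e[order(e[, 1]), , drop = FALSE]
    }
    data.frame(gene_id = gene, contig = contig,
               strand = if (revcomp) "-" else "+",
               start = at + e[, 1], end = at + e[, 2])
}

#' Build the ancestral/recombinant locus pair
#'
#' The recombinant haplotype is a deletion-type recombination of the
#' ancestral one: `ancestral[0, p)` fused to `ancestral[q, n)`, where
#' `p` is the end of subtilisin exon 4 and `q` lies just upstream of
#' CHS1. Every base of the recombinant therefore exists in the
#' ancestral haplotype except across the single junction seam, so the
#' canonical k-mer difference (recombinant minus ancestral) is exactly
#' the set of junction-spanning k-mers — the property the downstream
#' anchoring analysis detects. The chimeric gene's new intron spans
#' from the exon-4 fusion point to a novel terminal exon annotated in
#' downstream intergenic sequence, and contains CHS1' and CHS3' (the
#' hairpin arms) in inverted orientation.
#'
#' @param blueprint A [LocusBlueprint-class].
#' @param k K-mer length at which the junction-privacy property is
#'   recorded (default 31).
#' @param nSnps Number of SNP sites planted in regions shared by both
#'   haplotypes (flanks), spaced > 2k bp apart and > 2k bp from any
#'   structural boundary.
#' @return A [LocusTruth-class].
#' @export
buildLocusPair <- function(blueprint, k = 31L, nSnps = 40L) {
    stopifnot(is(blueprint, "LocusBlueprint"))
    validObject(blueprint)
    b <- blueprint
    k <- as.integer(k)
    set.seed(stageSeed(b@seed, "locus"))

    nex <- length(b@subtilisinExons)
    subLen <- sum(b@subtilisinExons) +
        (nex - 1L) * b@subtilisinIntronLen

    ## paralog with conserved (mutated) exons but its own random
    ## intron -- CHS introns diverge fast; the CHS1/CHS3 arm pair is
    ## the unusual case whose intron identity stays high
    makeParalog <- function(chs1, exonRate) {
        e1 <- substr(chs1, 1L, b@chsIntronStart)
        e2 <- substr(chs1, b@chsIntronStart + b@chsIntronLen + 1L,
                     b@chsGeneLen)
        paste0(mutateDna(e1, exonRate), randomDna(b@chsIntronLen),
               mutateDna(e2, exonRate))
    }

    flankL <- randomDna(b@flankLen)
    subtilisin <- randomDna(subLen)
    spacerA <- randomDna(b@spacerLen)
    chs1 <- randomDna(b@chsGeneLen)
    spacer1 <- randomDna(b@spacerLen)
    chs3 <- revcompDna(mutateDna(chs1, 1 - b@chs13Identity))
    spacer2 <- randomDna(b@spacerLen)
    chs4 <- makeParalog(chs1, 0.15)
    spacer3 <- randomDna(b@spacerLen)
    chs7 <- makeParalog(chs1, 0.20)
    flankR <- randomDna(b@flankLen)

    identity13 <- seqIdentity(chs1, revcompDna(chs3))
    if (identity13 < 0.95)
        stop("realized CHS1'/CHS3' identity ", round(identity13, 4),
             " < 0.95; hairpin assumption broken")

    parts <- c(flankL, subtilisin, spacerA, chs1, spacer1, chs3,
               spacer2, chs4, spacer3, chs7, flankR)
    offs <- cumsum(c(0L, nchar(parts)))  # 0-based starts
    names(offs) <- c("flankL", "subtilisin", "spacerA", "chs1", "spacer1",
                     "chs3", "spacer2", "chs4", "spacer3", "chs7",
                     "flankR", "endpos")
    ancestral <- paste(parts, collapse = "")
    n <- nchar(ancestral)

    ## subtilisin exon coordinates (absolute, 0-based half-open)
    exStart <- offs[["subtilisin"]] +
        cumsum(c(0L, head(b@subtilisinExons, -1) + b@subtilisinIntronLen))
    exEnd <- exStart + b@subtilisinExons

    ## recombination: prefix ends at exon-4 end; suffix starts a short
    ## margin upstream of CHS1 (the margin becomes the intron head).
    ## The suffix start is chosen so the bases flanking the seam differ
    ## from the ancestral continuations on both sides; every
    ## seam-spanning window then differs from its junction-adjacent
    ## ancestral counterpart, which makes the junction k-mers novel.
    p <- exEnd[4]
    base <- function(i) substr(ancestral, i + 1L, i + 1L)  # 0-based
    q <- NA_integer_
    for (cand in (offs[["chs1"]] - 150L):(offs[["chs1"]] - 110L)) {
        if (base(cand) != base(p) && base(cand - 1L) != base(p - 1L)) {
            q <- cand
            break
        }
    }
    if (is.na(q)) stop("no junction placement with distinct seam bases")
    stopifnot(q > p)
    recombinant <- paste0(substr(ancestral, 1L, p),
                          substr(ancestral, q + 1L, n))
    shift <- q - p  # ancestral pos >= q maps to pos - shift
    m <- nchar(recombinant)
    ## defensive check of the junction-privacy guarantee: no
    ## seam-spanning canonical k-mer may occur in the ancestral
    ## haplotype
    seam0 <- (p - k + 1L):(p - 1L)
    seamK <- cpp_canonicalize(substring(recombinant, seam0 + 1L,
                                        seam0 + k))
    ancK <- cpp_count_kmers(ancestral, k, canonical = TRUE)$kmer
    if (any(seamK %in% ancK))
        stop("junction k-mers collide with ancestral sequence; ",
             "choose a different seed")

    ## gene models -------------------------------------------------------
    gm <- list()
    gm[[1]] <- data.frame(gene_id = "subtilisin", contig = "ancestral",
                          strand = "+", start = exStart, end = exEnd)
    gm[[2]] <- chsExonRows("CHS1", "ancestral", offs[["chs1"]],
                           b@chsGeneLen, b@chsIntronStart, b@chsIntronLen)
    gm[[3]] <- chsExonRows("CHS3", "ancestral", offs[["chs3"]],
                           b@chsGeneLen, b@chsIntronStart, b@chsIntronLen,
                           revcomp = TRUE)
    gm[[4]] <- chsExonRows("CHS4", "ancestral", offs[["chs4"]],
                           b@chsGeneLen, b@chsIntronStart, b@chsIntronLen)
    gm[[9]] <- chsExonRows("CHS7", "ancestral", offs[["chs7"]],
                           b@chsGeneLen, b@chsIntronStart, b@chsIntronLen)

    ## chimeric gene on the recombinant: subtilisin exons 1-4 (prefix
    ## coordinates unchanged) + novel terminal exon in spacer2.
    novelStart <- offs[["spacer2"]] - shift + 120L
    gm[[5]] <- data.frame(gene_id = "SC1C3", contig = "recombinant",
                          strand = "+",
                          start = c(exStart[1:4], novelStart),
                          end = c(exEnd[1:4], novelStart + b@novelExonLen))
    ## CHS paralogs as they appear on the recombinant
    gm[[6]] <- chsExonRows("CHS1p", "recombinant", offs[["chs1"]] - shift,
                           b@chsGeneLen, b@chsIntronStart, b@chsIntronLen)
    gm[[7]] <- chsExonRows("CHS3p", "recombinant", offs[["chs3"]] - shift,
                           b@chsGeneLen, b@chsIntronStart, b@chsIntronLen,
                           revcomp = TRUE)
    gm[[8]] <- chsExonRows("CHS4p", "recombinant", offs[["chs4"]] - shift,
                           b@chsGeneLen, b@chsIntronStart, b@chsIntronLen)
    gm[[10]] <- chsExonRows("CHS7p", "recombinant", offs[["chs7"]] - shift,
                            b@chsGeneLen, b@chsIntronStart, b@chsIntronLen)
    geneModels <- do.call(rbind, gm)
    rownames(geneModels) <- NULL

    ## chimeric transcript junctions (0-based half-open boundaries)
    sc <- geneModels[geneModels$gene_id == "SC1C3", ]
    chimericJunctions <- data.frame(
        donor_end = sc$end[-nrow(sc)],
        acceptor_start = sc$start[-1])

    ## planted SNPs in both flanks, clear of every structural boundary
    pad <- 2L * k
    cand <- c(seq(pad, b@flankLen - pad, by = pad + 10L),
              seq(offs[["flankR"]] + pad, n - pad, by = pad + 10L))
    pos <- sort(sample(cand, min(nSnps, length(cand))))
    ref <- substring(ancestral, pos + 1L, pos + 1L)
    alt <- vapply(ref, function(bse) sample(setdiff(DNA_BASES, bse), 1L),
                  character(1), USE.NAMES = FALSE)
    snpSites <- data.frame(pos = as.integer(pos), ref = ref, alt = alt)

    regions <- data.frame(
        contig = c("ancestral", "ancestral", "ancestral", "ancestral",
                   "ancestral", "recombinant", "recombinant",
                   "recombinant", "recombinant", "recombinant"),
        name = c("subtilisin", "chs1", "chs3", "chs4", "deleted_segment",
                 "chimeric_gene", "chimeric_intron", "chs1_arm",
                 "chs3_arm", "novel_exon"),
        start = c(offs[["subtilisin"]], offs[["chs1"]], offs[["chs3"]],
                  offs[["chs4"]], p,
                  exStart[1], p, offs[["chs1"]] - shift,
                  offs[["chs3"]] - shift, novelStart),
        end = c(offs[["subtilisin"]] + subLen,
                offs[["chs1"]] + b@chsGeneLen,
                offs[["chs3"]] + b@chsGeneLen,
                offs[["chs4"]] + b@chsGeneLen, q,
                novelStart + b@novelExonLen, novelStart,
                offs[["chs1"]] - shift + b@chsGeneLen,
                offs[["chs3"]] - shift + b@chsGeneLen,
                novelStart + b@novelExonLen))

    truth <- new("LocusTruth",
                 ancestralSeq = ancestral, recombinantSeq = recombinant,
                 junctionPos = as.integer(p), geneModels = geneModels,
                 snpSites = snpSites,
                 chimericJunctions = chimericJunctions,
                 regions = regions, k = k)
    validObject(truth)
    truth
}

#' Junction-spanning canonical k-mers of a locus pair
#'
#' The canonical k-mers of every window of the recombinant haplotype
#' that covers both sides of the recombination seam (the last prefix
#' base and the first suffix base). These are the k-mers absent from
#' the ancestral haplotype — the synthetic analogue of the k-mer that
#' tags the I-locus recombination.
#'
#' @param truth A [LocusTruth-class].
#' @param k K-mer length (default: the length recorded on `truth`).
#' @return Character vector of unique canonical k-mers.
#' @export
junctionKmers <- function(truth, k = NULL) {
    stopifnot(is(truth, "LocusTruth"))
    if (is.null(k)) k <- truth@k
    p <- truth@junctionPos  # first suffix base, 0-based
    starts0 <- seq(p - k + 1L, p - 1L)  # cover bases p-1 and p
    w <- substring(truth@recombinantSeq, starts0 + 1L, starts0 + k)
    unique(canonicalizeKmer(w))
}

#' Haplotype sequences of one cohort accession
#'
#' Applies the accession's locus allele (ancestral or recombinant
#' backbone) and its planted-SNP genotype to produce the two haplotype
#' sequences reads are simulated from. SNP coordinates are defined on
#' the ancestral haplotype and lifted onto the recombinant across the
#' deleted segment.
#'
#' @param truth A [LocusTruth-class].
#' @param allele "ancestral" or "recombinant".
#' @param genotypes Character vector over sites ("0/0", "0/1", "1/1"),
#'   in `snpSites(truth)` order.
#' @return Character vector of the two haplotype sequences.
#' @export
sampleHaplotypes <- function(truth, allele, genotypes) {
    stopifnot(is(truth, "LocusTruth"),
              allele %in% c("ancestral", "recombinant"))
    sites <- truth@snpSites
    stopifnot(length(genotypes) == nrow(sites))
    base <- if (allele == "ancestral") truth@ancestralSeq
            else truth@recombinantSeq
    pos <- sites$pos
    if (allele == "recombinant") {
        del <- truth@regions[truth@regions$name == "deleted_segment", ]
        shift <- del$end - del$start
        keep <- pos < del$start | pos >= del$end
        pos <- ifelse(pos >= del$end, pos - shift, pos)
        pos[!keep] <- NA_integer_
    }
    hap <- c(base, base)
    alleleChar <- function(gtSide) {
        ifelse(gtSide == "1", sites$alt, sites$ref)
    }
    gt <- strsplit(genotypes, "/", fixed = TRUE)
    side1 <- vapply(gt, `[`, character(1), 1L)
    side2 <- vapply(gt, `[`, character(1), 2L)
    for (h in 1:2) {
        bases <- alleleChar(if (h == 1) side1 else side2)
        for (i in seq_along(pos)) {
            if (is.na(pos[i]) || bases[i] == sites$ref[i]) next
            substr(hap[h], pos[i] + 1L, pos[i] + 1L) <- bases[i]
        }
    }
    hap
}
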