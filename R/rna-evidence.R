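#' Construct a GeneModel
#'
#' @param geneId Gene label.
#' @param contig Contig name.
#' @param strand "+" or "-".
#' @param starts,ends Exon coordinates, 0-based half-open, sorted.
#' @return A [GeneModel-class].
#' @export
geneModel <- function(geneId, contig, strand, starts, ends) {
    new("GeneModel", geneId = geneId, contig = contig, strand = strand,
        exons = IRanges::IRanges(start = as.integer(starts) + 1L,
                                 end = as.integer(ends)))
}

#' Gene models of a locus truth as GeneModel objects
#'
#' @param truth A [LocusTruth-class].
#' @param contig Restrict to "ancestral" or "recombinant" (default all).
#' @return Named list of [GeneModel-class].
#' @export
truthGeneModels <- function(truth, contig = NULL) {
    gm <- geneModels(truth)
    if (!is.null(contig)) gm <- gm[gm$contig %in% contig, ]
    out <- lapply(split(gm, gm$gene_id), function(e) {
        e <- e[order(e$start), ]
        geneModel(e$gene_id[1], e$contig[1], e$strand[1], e$start, e$end)
    })
    out[unique(gm$gene_id)]
}

#' Detect the 3' adapter of a small-RNA library
#'
#' The candidate adapter seed is the most frequent probe-length window
#' over all reads that is absent (canonically) from the reference
#' index — genomic k-mers cannot be the adapter. The seed must occur
#' in at least `minFrac` of reads and is extended greedily rightward
#' while the extension keeps that support.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of raw
#'   small-RNA reads.
#' @param refIndex A [ReferenceKmerIndex-class] built at `k =
#'   probeLen` over the reference the library derives from.
#' @param probeLen Probe window length (default 12).
#' @param minFrac Minimum fraction of reads supporting the adapter.
#' @return An [AdapterCall-class]; `found = FALSE` when no candidate
#'   clears the support threshold.
#' @export
detectAdapter <- function(reads, refIndex, probeLen = 12L,
                          minFrac = 0.2) {
    reads <- readsAsCharacter(reads)
    if (!length(reads)) stop("no reads supplied")
    stopifnot(is(refIndex, "ReferenceKmerIndex"),
              kmerLength(refIndex) == probeLen)
    nReads <- length(reads)
    res <- cpp_count_kmers(reads, as.integer(probeLen), canonical = FALSE)
    cand <- data.frame(kmer = res$kmer, count = res$count)
    genomic <- cand$kmer %in% refIndex@table$kmer |
        canonicalizeKmer(cand$kmer) %in% refIndex@table$kmer
    cand <- cand[!genomic, , drop = FALSE]
    cand <- cand[order(-cand$count), , drop = FALSE]
    notFound <- new("AdapterCall", adapter = "", support = 0L,
                    fraction = 0, found = FALSE)
    if (!nrow(cand)) return(notFound)
    support <- function(s) sum(grepl(s, reads, fixed = TRUE))
    seed <- cand$kmer[1]
    supp <- support(seed)
    if (supp < minFrac * nReads) return(notFound)
    adapter <- seed
    ## extend leftward to the adapter start: inside the adapter the
    ## preceding base is (near-)fixed across reads, while upstream of
    ## the start it is random insert sequence, so its majority
    ## fraction collapses
    repeat {
        withPrev <- regmatches(reads, regexpr(paste0(".", adapter),
                                              reads))
        if (length(withPrev) < 0.5 * supp) break
        prev <- substring(withPrev, 1L, 1L)
        best <- names(which.max(table(prev)))
        if (max(table(prev)) < 0.6 * length(prev)) break
        extended <- paste0(best, adapter)
        suppExt <- support(extended)
        if (suppExt < minFrac * nReads) break
        adapter <- extended
        supp <- suppExt
    }
    repeat {
        withNext <- regmatches(reads, regexpr(paste0(adapter, "."),
                                              reads))
        if (!length(withNext)) break
        nxt <- substring(withNext, nchar(adapter) + 1L)
        best <- names(which.max(table(nxt)))
        extended <- paste0(adapter, best)
        suppExt <- support(extended)
        if (suppExt < minFrac * nReads) break
        adapter <- extended
        supp <- suppExt
    }
    new("AdapterCall", adapter = adapter, support = as.integer(supp),
        fraction = supp / nReads, found = TRUE)
}

#' Trim a 3' adapter and length-filter small-RNA reads
#'
#' Each read is cut at the first exact occurrence of the adapter's
#' leading 8-mer; trimmed reads outside the retained length range
#' (default 14-43 nt, the size range of a typical trimmed small-RNA
#' library) are discarded and the discard counts reported.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet].
#' @param adapter Adapter sequence (>= 8 nt).
#' @param minLen,maxLen Retained trimmed-length range.
#' @return List: `reads` (named character vector of trimmed inserts),
#'   `nShort`, `nLong`, `nNoAdapter`.
#' @export
trimAdapter <- function(reads, adapter, minLen = 14L, maxLen = 43L) {
    if (nchar(adapter) < 8L) stop("adapter must be >= 8 nt")
    reads <- readsAsCharacter(reads)
    key <- substr(adapter, 1L, 8L)
    cut <- regexpr(key, reads, fixed = TRUE)
    trimmed <- ifelse(cut > 0, substr(reads, 1L, cut - 1L), reads)
    len <- nchar(trimmed)
    keep <- len >= minLen & len <= maxLen
    list(reads = trimmed[keep],
         nShort = sum(len < minLen),
         nLong = sum(len > maxLen),
         nNoAdapter = sum(cut < 0))
}

#' Map reads by exact occurrence (no mismatches allowed)
#'
#' Reports every exact occurrence of every read on either strand of
#' the reference — the analogue of zero-mismatch short-read mapping.
#' Multi-mappers are all reported rather than assigned: hairpin-arm
#' ambiguity (a read matching both CHS1' and CHS3') is part of the
#' signal.
#'
#' @param reads Named character vector or [Biostrings::DNAStringSet]
#'   of trimmed reads.
#' @param reference Named character vector, DNAStringSet, or FASTA
#'   path.
#' @return data.frame: read, contig, start (0-based), width, strand.
#'   Reads with zero occurrences are absent (unmapped).
#' @export
mapReadsExact <- function(reads, reference) {
    reads <- readsAsCharacter(reads)
    if (is.null(names(reads)))
        names(reads) <- paste0("read", seq_along(reads))
    ref <- referenceAsCharacter(reference)
    refSet <- Biostrings::DNAStringSet(ref)
    uniq <- unique(reads)
    hitL <- list()
    for (w in unique(nchar(uniq))) {
        u <- uniq[nchar(uniq) == w]
        for (strand in c("+", "-")) {
            qry <- if (strand == "+") u else revcompDna(u)
            pd <- Biostrings::PDict(Biostrings::DNAStringSet(qry))
            for (ctg in names(ref)) {
                m <- Biostrings::matchPDict(pd, refSet[[ctg]])
                cnt <- S4Vectors::elementNROWS(m)
                if (!sum(cnt)) next
                st <- unlist(IRanges::start(m))
                hitL[[length(hitL) + 1L]] <- data.frame(
                    seq = rep(u, cnt), contig = ctg,
                    start = st - 1L, width = w, strand = strand)
            }
        }
    }
    if (!length(hitL))
        return(data.frame(read = character(), contig = character(),
                          start = integer(), width = integer(),
                          strand = character()))
    hits <- do.call(rbind, hitL)
    ## expand per read occurrence of each unique sequence
    idx <- split(seq_along(reads), reads)
    reps <- lengths(idx)[hits$seq]
    out <- data.frame(
        read = names(reads)[unlist(idx[hits$seq], use.names = FALSE)],
        contig = rep(hits$contig, reps),
        start = rep(hits$start, reps),
        width = rep(hits$width, reps),
        strand = rep(hits$strand, reps))
    rownames(out) <- NULL
    out
}

#' Count junction-spanning mRNA reads
#'
#' A read spans a junction if it matches exactly the concatenation of
#' at least `anchor` bp of the donor exon's 3' end and at least
#' `anchor` bp of the acceptor exon's 5' start (either strand). Counts
#' are flagged against the minimum junction coverage (default 5, the
#' conventional evidence bar for a supported splice junction).
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of mRNA
#'   reads.
#' @param contigSeq Sequence of the contig the gene lies on.
#' @param junctions data.frame with donor_end and acceptor_start
#'   (0-based half-open exon boundaries), e.g.
#'   `chimericJunctions(truth)`.
#' @param anchor Minimum exact overlap on each side, bp.
#' @param minCoverage Minimum spanning-read count to pass.
#' @return data.frame: donor_end, acceptor_start, count, passes_min.
#' @export
countJunctionReads <- function(reads, contigSeq, junctions,
                               anchor = 8L, minCoverage = 5L) {
    reads <- readsAsCharacter(reads)
    if (!nrow(junctions))
        return(data.frame(donor_end = integer(),
                          acceptor_start = integer(),
                          count = integer(), passes_min = logical()))
    maxRl <- if (length(reads)) max(nchar(reads)) else 0L
    if (length(reads) && anchor > min(nchar(reads)))
        stop("anchor exceeds read length")
    counts <- integer(nrow(junctions))
    for (j in seq_len(nrow(junctions))) {
        dEnd <- junctions$donor_end[j]
        aStart <- junctions$acceptor_start[j]
        flank <- max(0L, maxRl - anchor)
        donor <- substring(contigSeq, dEnd - flank + 1L, dEnd)
        acceptor <- substring(contigSeq, aStart + 1L, aStart + flank)
        ctx <- paste0(donor, acceptor)
        seam <- nchar(donor)
        if (!length(reads)) next
        nSpan <- 0L
        for (i in seq_along(reads)) {
            rd <- reads[i]
            spans <- FALSE
            for (q in c(rd, revcompDna(rd))) {
                mm <- gregexpr(q, ctx, fixed = TRUE)[[1]]
                if (mm[1] == -1) next
                s0 <- mm - 1L
                e0 <- s0 + nchar(q)
                if (any(s0 <= seam - anchor & e0 >= seam + anchor)) {
                    spans <- TRUE
                    break
                }
            }
            if (spans) nSpan <- nSpan + 1L
        }
        counts[j] <- nSpan
    }
    data.frame(donor_end = junctions$donor_end,
               acceptor_start = junctions$acceptor_start,
               count = counts,
               passes_min = counts >= minCoverage)
}

#' Small-RNA depth profile and exon/intron partition over a gene
#'
#' Read-base depth is accumulated over each aligned read's interval
#' within the gene span. A read is intronic if it lies fully inside an
#' intron, exonic if fully inside an exon; straddling reads are
#' counted separately and excluded from the intronic fraction (so the
#' fraction reflects unambiguous attributions only).
#'
#' @param alignments data.frame from [mapReadsExact()].
#' @param gene A [GeneModel-class].
#' @return A [SmallRnaProfile-class].
#' @export
profileSmallRna <- function(alignments, gene) {
    stopifnot(is(gene, "GeneModel"))
    ex <- exons(gene)
    intr <- introns(gene)
    gStart <- min(IRanges::start(ex))
    gEnd <- max(IRanges::end(ex))
    span <- gEnd - gStart + 1L
    depth <- numeric(span)
    aln <- alignments[alignments$contig == gene@contig, , drop = FALSE]
    exonN <- 0L; intronN <- 0L; straddleN <- 0L
    if (nrow(aln)) {
        s1 <- aln$start + 1L          # 1-based inclusive
        e1 <- aln$start + aln$width
        overl <- e1 >= gStart & s1 <= gEnd
        aln <- aln[overl, , drop = FALSE]
        s1 <- s1[overl]; e1 <- e1[overl]
        if (nrow(aln)) {
            rr <- IRanges::IRanges(start = s1, end = e1)
            inExon <- IRanges::overlapsAny(rr, ex, type = "within")
            inIntron <- if (length(intr))
                IRanges::overlapsAny(rr, intr, type = "within")
                else rep(FALSE, length(rr))
            exonN <- sum(inExon)
            intronN <- sum(inIntron)
            straddleN <- sum(!inExon & !inIntron)
            lo <- pmax(s1, gStart) - gStart + 1L
            hi <- pmin(e1, gEnd) - gStart + 1L
            for (i in seq_along(lo))
                depth[lo[i]:hi[i]] <- depth[lo[i]:hi[i]] + 1
        }
    }
    denom <- exonN + intronN
    new("SmallRnaProfile", geneId = gene@geneId, depth = depth,
        exonReads = as.integer(exonN), intronReads = as.integer(intronN),
        straddleReads = as.integer(straddleN),
        intronicFraction = if (denom > 0) intronN / denom else NA_real_)
}

#' Perfect-match coverage between two paralog sequences
#'
#' Finds all maximal exact shared substrings of at least `minLen` bp
#' between the query and subject (both orientations), projects them
#' onto the subject, merges overlaps, and reports the covered fraction
#' — how much of a paralog a population of >= minLen-nt small RNAs
#' from the query could target by perfect complementarity.
#'
#' @param seqA Query sequence (character scalar).
#' @param seqB Subject sequence (character scalar).
#' @param minLen Minimum exact-match length, bp (default 20).
#' @param queryGene,subjectGene Labels for the report.
#' @return A [ParalogMatchReport-class].
#' @export
paralogPerfectMatchCoverage <- function(seqA, seqB, minLen = 20L,
                                        queryGene = "query",
                                        subjectGene = "subject") {
    minLen <- as.integer(minLen)
    stopifnot(nchar(seqA) >= minLen, nchar(seqB) >= minLen)
    nB <- nchar(seqB)
    endsFwd <- matchWindowEnds(seqA, seqB, minLen)
    endsRev <- matchWindowEnds(seqA, revcompDna(seqB), minLen)
    ir <- IRanges::IRanges()
    if (length(endsFwd))
        ir <- c(ir, IRanges::IRanges(start = endsFwd - minLen + 1L,
                                     end = endsFwd))
    if (length(endsRev))  # map rc(B) interval [s,e] back onto B
        ir <- c(ir, IRanges::IRanges(start = nB - endsRev + 1L,
                                     end = nB - (endsRev - minLen + 1L)
                                           + 1L))
    ir <- IRanges::reduce(ir)
    covered <- sum(IRanges::width(ir))
    new("ParalogMatchReport", queryGene = queryGene,
        subjectGene = subjectGene, minLen = minLen,
        coveredBp = as.integer(covered), fraction = covered / nB,
        intervals = ir)
}

## 1-based end positions j on B such that some common substring of A
## and B of length >= minLen ends at j. Diagonal run-length DP,
## vectorized over columns.
matchWindowEnds <- function(seqA, seqB, minLen) {
    a <- strsplit(seqA, "", fixed = TRUE)[[1]]
    b <- strsplit(seqB, "", fixed = TRUE)[[1]]
    nB <- length(b)
    prev <- integer(nB)
    hit <- logical(nB)
    for (i in seq_along(a)) {
        cur <- ifelse(a[i] == b, c(0L, prev[-nB]) + 1L, 0L)
        hit <- hit | cur >= minLen
        prev <- cur
    }
    which(hit)
}
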