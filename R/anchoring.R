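#' AnchorHit: exact-match localization of one k-mer
#'
#' @slot kmer The canonical k-mer queried.
#' @slot hits data.frame: reference, contig, offset (0-based), strand.
#' @slot anchored TRUE iff hits is nonempty.
#' @exportClass AnchorHit
setClass("AnchorHit",
    representation(kmer = "character", hits = "data.frame",
                   anchored = "logical"))

setMethod("show", "AnchorHit", function(object) {
    cat("AnchorHit |", object@kmer, "|",
        if (object@anchored) paste(nrow(object@hits), "hit(s)")
        else "unanchored", "\n")
})

#' Build an exact-match canonical k-mer index of a reference
#'
#' Indexes every canonical k-mer of every contig with its occurrence
#' positions — the exact-match surrogate for BLAST localization: a
#' 31-mer either occurs in the assembly or it does not.
#'
#' @param fasta Named character vector, [Biostrings::DNAStringSet], or
#'   FASTA path.
#' @param k K-mer length (default 31).
#' @param name Reference label.
#' @return A [ReferenceKmerIndex-class].
#' @export
buildReferenceIndex <- function(fasta, k = 31L, name = "reference") {
    k <- as.integer(k)
    seqs <- referenceAsCharacter(fasta)
    if (!any(nchar(seqs) >= k)) stop("no contig of length >= k")
    tabs <- lapply(names(seqs), function(ctg) {
        res <- cpp_kmer_positions(seqs[[ctg]], k)
        data.table::data.table(kmer = res$kmer, contig = ctg,
                               offset = res$offset, strand = res$strand)
    })
    tab <- data.table::rbindlist(tabs)
    data.table::setkey(tab, kmer)
    new("ReferenceKmerIndex", name = name, k = k, table = tab)
}

referenceAsCharacter <- function(fasta) {
    if (is(fasta, "DNAStringSet")) {
        out <- as.character(fasta)
    } else if (is.character(fasta) && length(fasta) == 1 &&
               is.null(names(fasta)) && file.exists(fasta)) {
        out <- as.character(Biostrings::readDNAStringSet(fasta))
    } else if (is.character(fasta)) {
        out <- fasta
        if (is.null(names(out)))
            names(out) <- paste0("contig", seq_along(out))
    } else stop("unsupported reference input")
    out
}

#' Anchor one k-mer against reference indexes
#'
#' Aggregates exact-match hits across all supplied indexes; a k-mer
#' with no hit anywhere is unanchored — at genome scale, the signature
#' of a structural junction missing from the assemblies.
#'
#' @param kmer A single k-mer (canonicalized before lookup).
#' @param indexes A [ReferenceKmerIndex-class] or list of them.
#' @return An [AnchorHit-class].
#' @export
anchorKmer <- function(kmer, indexes) {
    if (is(indexes, "ReferenceKmerIndex")) indexes <- list(indexes)
    stopifnot(length(kmer) == 1L)
    ks <- vapply(indexes, kmerLength, 1L)
    if (any(nchar(kmer) != ks))
        stop("k-mer length does not match index k")
    key <- canonicalizeKmer(kmer)
    hits <- lapply(indexes, function(idx) {
        h <- idx@table[list(key), nomatch = NULL]
        if (nrow(h))
            data.frame(reference = idx@name, contig = h$contig,
                       offset = h$offset, strand = h$strand)
        else NULL
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits))
        hits <- data.frame(reference = character(), contig = character(),
                           offset = integer(), strand = character())
    new("AnchorHit", kmer = key, hits = hits, anchored = nrow(hits) > 0)
}

#' Partition significant k-mers into anchored and unanchored
#'
#' Every Bonferroni-significant k-mer of a GWAS result is assigned to
#' exactly one class: anchored (with its exact-match positions) or
#' unanchored (candidate structural-variant k-mers, sorted by p).
#'
#' @param result A [GwasResult-class].
#' @param indexes A [ReferenceKmerIndex-class] or list of them.
#' @return List with elements `anchored` (data.frame kmer, p),
#'   `positions` (data.frame kmer, reference, contig, offset, strand)
#'   and `unanchored` (data.frame kmer, p, ascending p).
#' @export
classifySignificantKmers <- function(result, indexes) {
    stopifnot(is(result, "GwasResult"))
    if (is(indexes, "ReferenceKmerIndex")) indexes <- list(indexes)
    rec <- records(result)
    sig <- rec[rec$significant, c("kmer", "p")]
    if (!nrow(rec)) stop("empty GWAS result")
    posL <- list()
    inAny <- rep(FALSE, nrow(sig))
    for (idx in indexes) {
        h <- idx@table[list(sig$kmer), nomatch = NULL]
        if (nrow(h)) {
            inAny <- inAny | sig$kmer %in% h$kmer
            posL[[length(posL) + 1L]] <-
                data.frame(kmer = h$kmer, reference = idx@name,
                           contig = h$contig, offset = h$offset,
                           strand = h$strand)
        }
    }
    positions <- if (length(posL)) do.call(rbind, posL) else
        data.frame(kmer = character(), reference = character(),
                   contig = character(), offset = integer(),
                   strand = character())
    unanch <- sig[!inAny, , drop = FALSE]
    unanch <- unanch[order(unanch$p, unanch$kmer, method = "radix"), ]
    rownames(unanch) <- NULL
    list(anchored = sig[inAny, , drop = FALSE],
         positions = positions, unanchored = unanch)
}

#' Ref/alt k-mer pairs for SNP sites
#'
#' For each biallelic site, the canonical k-mers of every k-window
#' overlapping the site with the reference base, and the same windows
#' with the alternate base. Sites whose window overlaps another listed
#' variant are skipped (ambiguous pairing), as are sites too close to
#' a sequence end.
#'
#' @param refSeq Reference sequence (character scalar) the site
#'   coordinates refer to.
#' @param sites data.frame with columns pos (0-based), ref, alt.
#' @param k K-mer length.
#' @return List of site entries: site name, pos, ref, alt, refKmers,
#'   altKmers.
#' @export
buildSiteKmerPairs <- function(refSeq, sites, k = 31L) {
    n <- nchar(refSeq)
    out <- list()
    for (i in seq_len(nrow(sites))) {
        pos <- sites$pos[i]
        if (substring(refSeq, pos + 1L, pos + 1L) != sites$ref[i])
            stop("ref base mismatch at site ", i)
        near <- abs(sites$pos - pos) < k & seq_len(nrow(sites)) != i
        if (any(near)) next
        lo <- max(0L, pos - k + 1L)
        hi <- min(pos, n - k)
        if (hi < lo) next
        starts <- lo:hi
        refW <- substring(refSeq, starts + 1L, starts + k)
        altSeq <- refSeq
        substr(altSeq, pos + 1L, pos + 1L) <- sites$alt[i]
        altW <- substring(altSeq, starts + 1L, starts + k)
        refK <- unique(canonicalizeKmer(refW))
        altK <- unique(canonicalizeKmer(altW))
        if (length(intersect(refK, altK))) next  # degenerate pairing
        out[[length(out) + 1L]] <-
            list(site = sprintf("%s:%d:%s>%s", "ancestral", pos + 1L,
                                sites$ref[i], sites$alt[i]),
                 pos = pos, ref = sites$ref[i], alt = sites$alt[i],
                 refKmers = refK, altKmers = altK)
    }
    out
}

#' Infer site genotypes from a sample's k-mer set
#'
#' Presence of only reference k-mers calls ref/ref, only alternate
#' k-mers alt/alt, both het, neither missing. Het calling from k-mer
#' presence extends pure presence/absence genotyping so diploid
#' concordance is well-defined.
#'
#' @param pairs Output of [buildSiteKmerPairs()] (same k as the set).
#' @param sampleSet A [SampleKmerSet-class].
#' @return Character vector over sites: "0/0", "1/1", "0/1", "missing";
#'   names are site labels.
#' @export
inferSiteGenotypesFromKmers <- function(pairs, sampleSet) {
    stopifnot(is(sampleSet, "SampleKmerSet"))
    set <- kmers(sampleSet)
    out <- vapply(pairs, function(pr) {
        hasRef <- any(pr$refKmers %in% set)
        hasAlt <- any(pr$altKmers %in% set)
        if (hasRef && hasAlt) "0/1"
        else if (hasRef) "0/0"
        else if (hasAlt) "1/1"
        else "missing"
    }, character(1))
    names(out) <- vapply(pairs, `[[`, character(1), "site")
    out
}

#' Genotype concordance between k-mer calls and reference-based calls
#'
#' Percent of non-missing genotype pairs that agree, with a per-site
#' breakdown. Missing genotypes on either side are excluded from the
#' denominator; zero comparable genotypes is an error, not 0 percent.
#'
#' @param kmerCalls Character matrix sites x samples ("0/0", "0/1",
#'   "1/1", "missing"), dimnames required.
#' @param referenceCalls Same shape, or a VCF path (GT field read via
#'   `VariantAnnotation`; "./." treated as missing).
#' @return A [ConcordanceReport-class].
#' @export
genotypeConcordance <- function(kmerCalls, referenceCalls) {
    if (is.character(referenceCalls) && length(referenceCalls) == 1 &&
        file.exists(referenceCalls)) {
        vcf <- VariantAnnotation::readVcf(referenceCalls)
        gt <- VariantAnnotation::geno(vcf)$GT
        gt[gt %in% c("./.", ".")] <- "missing"
        gt[gt == "1/0"] <- "0/1"
        referenceCalls <- gt
    }
    sites <- intersect(rownames(kmerCalls), rownames(referenceCalls))
    samp <- intersect(colnames(kmerCalls), colnames(referenceCalls))
    if (!length(sites) || !length(samp))
        stop("no shared sites/samples between call sets")
    a <- kmerCalls[sites, samp, drop = FALSE]
    b <- referenceCalls[sites, samp, drop = FALSE]
    ok <- a != "missing" & b != "missing"
    nComp <- sum(ok)
    if (nComp == 0L) stop("zero comparable genotypes")
    match_ <- ok & a == b
    perSite <- data.frame(site = sites,
                          compared = rowSums(ok),
                          matching = rowSums(match_))
    new("ConcordanceReport", nSites = length(sites),
        nGenotypes = as.integer(nComp),
        nMatching = as.integer(sum(match_)),
        percent = 100 * sum(match_) / nComp,
        perSite = perSite)
}
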