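#' Build the k-mer presence/absence matrix
#'
#' Rows are the union of the per-sample canonical k-mer sets, in
#' lexicographic order; a row is retained only if its presence
#' frequency lies inside the polymorphism band `[minFreq, 1 - minFreq]`
#' (the presence/absence analogue of a MAF filter — monomorphic and
#' near-monomorphic k-mers carry no association information).
#'
#' @param sets List of [SampleKmerSet-class], all with the same k.
#' @param minFreq Lower presence-frequency bound (default 0.05).
#' @return A [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(sets, minFreq = 0.05) {
    stopifnot(length(sets) >= 2L,
              all(vapply(sets, is, TRUE, "SampleKmerSet")))
    ks <- vapply(sets, kmerLength, 1L)
    if (length(unique(ks)) != 1L)
        stop("all sample sets must share the same k")
    ids <- vapply(sets, sampleId, character(1))
    if (anyDuplicated(ids)) stop("duplicate sample ids")
    allK <- sort(unique(unlist(lapply(sets, kmers), use.names = FALSE)),
                 method = "radix")
    pres <- matrix(FALSE, nrow = length(allK), ncol = length(sets),
                   dimnames = list(NULL, ids))
    for (j in seq_along(sets))
        pres[match(kmers(sets[[j]]), allK), j] <- TRUE
    freq <- rowMeans(pres)
    keep <- freq >= minFreq & freq <= 1 - minFreq
    new("PresenceMatrix", kmers = allK[keep], sampleIds = ids,
        presence = unname(pres[keep, , drop = FALSE]),
        freq = unname(freq[keep]), k = ks[1], minFreq = minFreq)
}

#' Assemble a presence matrix directly from logical columns
#'
#' Constructor for callers that already have presence indicators (e.g.
#' calibration studies); applies the same frequency band as
#' [buildPresenceMatrix()].
#'
#' @param presence Logical matrix, k-mers x samples, rownames = k-mers,
#'   colnames = sample ids.
#' @param k K-mer length of the row keys.
#' @param minFreq Polymorphism band bound.
#' @return A [PresenceMatrix-class].
#' @export
presenceMatrix <- function(presence, k = 31L, minFreq = 0.05) {
    stopifnot(is.matrix(presence), is.logical(presence),
              !is.null(rownames(presence)), !is.null(colnames(presence)))
    ord <- order(rownames(presence), method = "radix")
    presence <- presence[ord, , drop = FALSE]
    freq <- rowMeans(presence)
    keep <- freq >= minFreq & freq <= 1 - minFreq
    new("PresenceMatrix", kmers = rownames(presence)[keep],
        sampleIds = colnames(presence),
        presence = unname(presence[keep, , drop = FALSE]),
        freq = unname(freq[keep]), k = as.integer(k), minFreq = minFreq)
}

#' Write a presence matrix as a pseudo-VCF
#'
#' One biallelic record per k-mer on the synthetic contig "KMERS":
#' POS is the 1-based ordinal rank of the k-mer in row order, ID the
#' k-mer sequence, REF/ALT the placeholder pair A/T, and genotypes are
#' "1/1" (present) or "0/0" (absent). The encoding round-trips
#' losslessly through a standards-compliant VCF parser.
#'
#' @param matrix A [PresenceMatrix-class] (nonempty).
#' @param out Output path.
#' @return Invisibly, the path.
#' @export
writePseudoVcf <- function(matrix, out) {
    stopifnot(is(matrix, "PresenceMatrix"))
    if (!length(matrix@kmers)) stop("presence matrix is empty")
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=KMERS,length=%d>",
                     length(matrix@kmers)),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             sprintf("##kseed_k=%d", matrix@k),
             sprintf("##kseed_minFreq=%g", matrix@minFreq),
             paste0("##kseed_note=presence/absence pseudo-genotypes; ",
                    "association downstream is uncorrected for ",
                    "kinship/structure"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", matrix@sampleIds),
                   collapse = "\t"))
    gt <- ifelse(matrix@presence, "1/1", "0/0")
    body <- paste(
        "KMERS", seq_along(matrix@kmers), matrix@kmers, "A", "T", ".",
        ".", ".", "GT",
        apply(gt, 1L, paste, collapse = "\t"),
        sep = "\t")
    writeLines(c(hdr, body), out)
    invisible(out)
}

#' Read a pseudo-VCF back into a presence matrix
#'
#' Parses with `VariantAnnotation` (a standards-compliant VCF reader),
#' recovering the matrix [writePseudoVcf()] emitted.
#'
#' @param path Pseudo-VCF path.
#' @return A [PresenceMatrix-class].
#' @export
readPseudoVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    kmersIn <- rownames(vcf)
    hdr <- VariantAnnotation::meta(VariantAnnotation::header(vcf))
    kLine <- hdr$kseed_k
    k <- if (!is.null(kLine)) as.integer(kLine[1, 1]) else
         as.integer(nchar(kmersIn[1]))
    mfLine <- hdr$kseed_minFreq
    minFreq <- if (!is.null(mfLine)) as.numeric(mfLine[1, 1]) else 0
    pres <- gt == "1/1"
    rownames(pres) <- kmersIn
    presenceMatrix(pres, k = k, minFreq = minFreq)
}

#' Enumerate case/control bipartitions of trait categories
#'
#' One [Binarization-class] per unordered bipartition of the category
#' set into two nonempty parts: `2^(c-1) - 1` bipartitions for `c`
#' categories. Samples with a missing label for the trait are excluded;
#' bipartitions leaving either side without samples are dropped with a
#' warning.
#'
#' @param traits data.frame with an `accession_id` column and one
#'   column per trait.
#' @param trait Trait column to binarize.
#' @param categories Category labels (default: observed labels).
#' @return List of [Binarization-class].
#' @export
enumerateBinarizations <- function(traits, trait,
                                   categories = NULL) {
    stopifnot(trait %in% names(traits))
    lab <- traits[[trait]]
    ok <- !is.na(lab) & lab != ""
    if (is.null(categories)) categories <- sort(unique(lab[ok]))
    cc <- length(categories)
    if (cc < 2L) stop("need >= 2 categories")
    out <- list()
    ## subsets of categories[-1] joined with categories[1] enumerate
    ## every unordered bipartition exactly once
    for (mask in 0:(2^(cc - 1L) - 1L)) {
        inCase <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(cc - 2L)))))
        caseCat <- categories[inCase]
        ctrlCat <- categories[!inCase]
        if (!length(ctrlCat)) next
        caseS <- traits$accession_id[ok & lab %in% caseCat]
        ctrlS <- traits$accession_id[ok & lab %in% ctrlCat]
        if (!length(caseS) || !length(ctrlS)) {
            warning("dropping bipartition {",
                    paste(caseCat, collapse = ","), "} vs {",
                    paste(ctrlCat, collapse = ","),
                    "}: one side has no samples")
            next
        }
        out[[length(out) + 1L]] <-
            new("Binarization", trait = trait,
                caseCategories = caseCat, controlCategories = ctrlCat,
                caseSamples = caseS, controlSamples = ctrlS)
    }
    out
}

#' Case/control binarization for one category set
#'
#' Convenience constructor: the named categories are cases, all other
#' observed categories controls.
#'
#' @inheritParams enumerateBinarizations
#' @param caseCategories Category labels forming the case side.
#' @return A [Binarization-class].
#' @export
binarizeTrait <- function(traits, trait, caseCategories) {
    lab <- traits[[trait]]
    ok <- !is.na(lab) & lab != ""
    ctrlCat <- setdiff(sort(unique(lab[ok])), caseCategories)
    new("Binarization", trait = trait,
        caseCategories = caseCategories, controlCategories = ctrlCat,
        caseSamples = traits$accession_id[ok & lab %in% caseCategories],
        controlSamples = traits$accession_id[ok & lab %in% ctrlCat])
}

#' Allelic chi-squared association on 2x2 presence counts
#'
#' Pearson chi-squared with 1 df and no continuity correction on the
#' case/control x presence/absence table — the basic allelic
#' case/control test. Degenerate margins (an all-zero row or column)
#' give chi2 = 0, p = 1. The odds ratio is `(a d)/(b c)`, with a 0.5
#' continuity substitute in every cell when any cell is zero.
#' Vectorized over tables.
#'
#' @param a Cases with the k-mer.
#' @param b Cases without.
#' @param c Controls with.
#' @param d Controls without.
#' @return data.frame with columns chi2, p, odds_ratio.
#' @examples
#' allelicAssociation(2, 152, 64, 3)  # the junction k-mer's table
#' @export
allelicAssociation <- function(a, b, c, d) {
    if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
    if (any(a + b < 1) || any(c + d < 1))
        stop("each of cases and controls must have >= 1 sample")
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    n <- a + b + c + d
    den <- (a + b) * (c + d) * (a + c) * (b + d)
    chi2 <- ifelse(den > 0, n * (a * d - b * c)^2 / den, 0)
    p <- ifelse(den > 0, pchisq(chi2, df = 1L, lower.tail = FALSE), 1)
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    or <- ifelse(zero,
                 ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
                 (a * d) / (b * c))
    data.frame(chi2 = chi2, p = p, odds_ratio = or)
}

#' Fisher's exact two-sided p for a 2x2 table (vectorized)
#'
#' Hypergeometric enumeration; reported alongside the chi-squared p
#' when any expected cell is below 5 (small-sample caveat), though
#' ranking always uses the chi-squared p.
#'
#' @inheritParams allelicAssociation
#' @return Numeric vector of p-values.
#' @export
fisherExactP <- function(a, b, c, d) {
    mapply(function(a, b, c, d) {
        lo <- max(0L, a + b - (b + d))
        hi <- min(a + b, a + c)
        x <- lo:hi
        px <- dhyper(x, a + c, b + d, a + b)
        sum(px[px <= dhyper(a, a + c, b + d, a + b) * (1 + 1e-7)])
    }, a, b, c, d)
}

#' Run the case/control k-mer GWAS
#'
#' One association record per retained k-mer; the significance
#' threshold is the Bonferroni cutoff `alpha / mTests` unless a fixed
#' override is supplied (the study-scale analogue is a plotted
#' threshold of 5e-9 at ~1e7 tests). Records are sorted by ascending
#' p with lexicographic k-mer tie-break.
#'
#' @param matrix A [PresenceMatrix-class].
#' @param binarization A [Binarization-class]; its samples must be a
#'   subset of the matrix samples.
#' @param alpha Family-wise error rate (default 0.05).
#' @param fixedThreshold Optional fixed p cutoff overriding Bonferroni.
#' @return A [GwasResult-class].
#' @export
runKmerGwas <- function(matrix, binarization, alpha = 0.05,
                        fixedThreshold = NULL) {
    stopifnot(is(matrix, "PresenceMatrix"), is(binarization, "Binarization"))
    caseS <- intersect(binarization@caseSamples, matrix@sampleIds)
    ctrlS <- intersect(binarization@controlSamples, matrix@sampleIds)
    if (!length(caseS) || !length(ctrlS))
        stop("case or control side empty after intersecting with matrix")
    pres <- matrix@presence
    a <- rowSums(pres[, match(caseS, matrix@sampleIds), drop = FALSE])
    c_ <- rowSums(pres[, match(ctrlS, matrix@sampleIds), drop = FALSE])
    b <- length(caseS) - a
    d <- length(ctrlS) - c_
    m <- length(matrix@kmers)
    threshold <- if (!is.null(fixedThreshold)) fixedThreshold else alpha / m
    assoc <- allelicAssociation(a, b, c_, d)
    n <- a + b + c_ + d
    expMin <- pmin((a + b) * (a + c_), (a + b) * (b + d),
                   (c_ + d) * (a + c_), (c_ + d) * (b + d)) / n
    fp <- rep(NA_real_, m)
    small <- which(expMin < 5)
    if (length(small))
        fp[small] <- fisherExactP(a[small], b[small], c_[small], d[small])
    rec <- data.frame(kmer = matrix@kmers, a = a, b = b, c = c_, d = d,
                      chi2 = assoc$chi2, p = assoc$p, fisher_p = fp,
                      odds_ratio = assoc$odds_ratio,
                      significant = assoc$p <= threshold)
    rec <- rec[order(rec$p, rec$kmer, method = "radix"), ]
    rownames(rec) <- NULL
    new("GwasResult", records = rec, binarization = binarization,
        mTests = as.integer(m), alpha = alpha, threshold = threshold)
}

#' Locus span in kbp from 1-based coordinates
#'
#' `round((end - start) / 1000)`, half away from zero — the arithmetic
#' behind printed locus sizes such as 182 kbp for a 53,087,195 to
#' 53,269,307 bp range.
#'
#' @param start,end 1-based bp coordinates, `end > start`.
#' @return Integer kbp.
#' @export
locusSpanKbp <- function(start, end) {
    if (any(end <= start)) stop("end must be > start")
    as.integer(floor((end - start) / 1000 + 0.5))
}
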