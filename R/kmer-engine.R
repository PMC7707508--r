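#' Canonicalize k-mers
#'
#' A canonical k-mer is the lexicographic minimum (A < C < G < T) of a
#' k-mer and its reverse complement, making counting strand-neutral.
#' Idempotent; rejects non-ACGT input (windows containing N are skipped
#' upstream by the counter, never canonicalized).
#'
#' @param seq Character vector of DNA strings over ACGT, each <= 32 bp.
#' @return Character vector of canonical forms.
#' @examples
#' canonicalizeKmer(c("ACG", "GTT", "ACGT"))  # "ACG" "AAC" "ACGT"
#' @export
canonicalizeKmer <- function(seq) {
    if (!length(seq)) return(character())
    if (any(is.na(seq)) || !all(grepl("^[ACGT]+$", seq)))
        stop("k-mers must contain only A, C, G, T")
    cpp_canonicalize(seq)
}

#' Count canonical k-mers in reads
#'
#' Every window of length `k` containing only ACGT contributes one count
#' to its canonical key; windows with any other symbol are skipped
#' entirely. Counting a read set and its reverse complement yields
#' identical tables.
#'
#' @param reads A character vector, a [Biostrings::DNAStringSet], or the
#'   path to a FASTQ/FASTA file (gzip accepted; format inferred from the
#'   extension, `.fq`/`.fastq` as FASTQ, otherwise FASTA).
#' @param k K-mer length, default 31; must be in [3, 32].
#' @param sampleId Sample label stored on the table.
#' @return A [KmerCountTable-class].
#' @examples
#' kmerCounts(countCanonicalKmers("ACGTT", k = 3))  # ACG:2, AAC:1
#' @export
countCanonicalKmers <- function(reads, k = 31L, sampleId = "sample") {
    k <- as.integer(k)
    if (k < 3L || k > 32L) stop("k must be in [3, 32]")
    seqs <- readsAsCharacter(reads)
    res <- cpp_count_kmers(seqs, k, canonical = TRUE)
    counts <- res$count
    names(counts) <- res$kmer
    counts <- counts[order(names(counts), method = "radix")]
    new("KmerCountTable", sampleId = sampleId, k = k, counts = counts)
}

#' Filter singleton k-mers from a count table
#'
#' K-mers counted fewer than `minCount` times are dropped (default 2:
#' singletons likely carry sequencing errors). `minCount = 1` is the
#' identity on the key set.
#'
#' @param table A [KmerCountTable-class].
#' @param minCount Minimum occurrence count to retain.
#' @return A [SampleKmerSet-class].
#' @export
filterMinCount <- function(table, minCount = 2L) {
    stopifnot(is(table, "KmerCountTable"))
    if (minCount < 1L) stop("minCount must be >= 1")
    counts <- table@counts
    keep <- names(counts)[counts >= minCount]
    new("SampleKmerSet", sampleId = table@sampleId, k = table@k,
        kmers = sort(keep, method = "radix"),
        nRaw = as.numeric(sum(counts)))
}

#' Count and filter in one step
#'
#' Convenience wrapper: [countCanonicalKmers()] then [filterMinCount()].
#'
#' @inheritParams countCanonicalKmers
#' @inheritParams filterMinCount
#' @return A [SampleKmerSet-class].
#' @export
sampleKmerSet <- function(reads, k = 31L, minCount = 2L,
                          sampleId = "sample") {
    filterMinCount(countCanonicalKmers(reads, k = k, sampleId = sampleId),
                   minCount = minCount)
}

## Accept character, DNAStringSet, or a file path.
readsAsCharacter <- function(reads) {
    if (is(reads, "DNAStringSet")) return(as.character(reads))
    if (is(reads, "XString")) return(as.character(reads))
    if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
        fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq"
               else "fasta"
        return(as.character(
            Biostrings::readDNAStringSet(reads, format = fmt)))
    }
    if (is.character(reads)) return(reads)
    stop("reads must be character, DNAStringSet, or a file path")
}
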