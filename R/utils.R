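#' @useDynLib kseed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats pchisq dhyper rbinom runif setNames
#' @importFrom utils write.table read.table head
#' @importFrom data.table data.table rbindlist setkey
NULL

.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string
#'
#' Uniform i.i.d. bases; used by the synthetic-locus builder. Draws from
#' the current RNG stream.
#'
#' @param n Length in bp.
#' @return A character scalar over ACGT.
#' @keywords internal
randomDna <- function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of character DNA
#'
#' Thin wrapper over Biostrings so plain character vectors round-trip
#' without the caller touching XString machinery.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcompDna <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## i.i.d. substitutions at rate `rate`; substituted base always differs
## from the original. Returns the mutated string.
mutateDna <- function(seq, rate) {
    if (rate <= 0) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < rate)
    if (length(hit)) {
        chars[hit] <- vapply(chars[hit], function(b) {
            sample(setdiff(DNA_BASES, b), 1L)
        }, character(1), USE.NAMES = FALSE)
    }
    paste(chars, collapse = "")
}

## Fan a single user seed out to independent per-stage streams.
## Offsets are fixed prime multipliers so stages stay decoupled;
## result kept inside 32-bit integer range.
stageSeed <- function(seed, stage) {
    offsets <- c(locus = 104729L, cohort = 224737L, wgr = 350377L,
                 mrna = 479909L, srna = 611953L, snp = 746773L,
                 noise = 882377L)
    if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
    as.integer((as.numeric(seed) + offsets[[stage]]) %% 2147483647)
}

## Alignment-free identity of two equal-length strings.
seqIdentity <- function(a, b) {
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    stopifnot(length(ca) == length(cb))
    mean(ca == cb)
}

## All k-windows of a character vector of sequences, as one character
## vector (windows containing non-ACGT are dropped). Pure R; the fast
## path is the compiled counter -- this helper serves small inputs.
kmerWindows <- function(seqs, k) {
    out <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        n <- nchar(seqs[i])
        if (n < k) next
        starts <- seq_len(n - k + 1L)
        w <- substring(seqs[i], starts, starts + k - 1L)
        out[[i]] <- w[grepl("^[ACGT]+$", w)]
    }
    unlist(out, use.names = FALSE)
}
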