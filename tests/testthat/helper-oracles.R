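## Independent pure-R oracles. These deliberately avoid the package's
## compiled code paths: reverse complement via chartr + rev, windows
## via substring, counting via table().

oracle_revcomp <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "",
                           fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
    rc <- oracle_revcomp(x)
    ifelse(x <= rc, x, rc)
}

## Naive quadratic canonical k-mer recount.
oracle_kmer_count <- function(seqs, k) {
    wins <- unlist(lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < k) return(character())
        starts <- seq_len(n - k + 1L)
        substring(s, starts, starts + k - 1L)
    }), use.names = FALSE)
    wins <- wins[grepl("^[ACGT]+$", wins)]
    if (!length(wins)) return(integer())
    tab <- table(oracle_canonical(wins))
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[order(names(out), method = "radix")]
}

## Exhaustive substring presence: is `kmer` (either strand) a
## substring of `seq`?
oracle_occurs <- function(kmer, seq) {
    grepl(kmer, seq, fixed = TRUE) |
        grepl(oracle_revcomp(kmer), seq, fixed = TRUE)
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = "")
}
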