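#' Read-simulation parameters
#'
#' @slot readLen Read length, bp (>= 31).
#' @slot depth Fold coverage (> 0); default 15, a realistic
#'   whole-genome-resequencing depth for a diversity panel.
#' @slot err Per-base substitution probability, in [0, 0.25).
#' @slot paired Paired-end flag (fixed 300 bp outer spacing).
#' @slot seed Integer seed.
#' @exportClass ReadSimParams
setClass("ReadSimParams",
    representation(readLen = "integer", depth = "numeric",
                   err = "numeric", paired = "logical", seed = "integer"))

setValidity("ReadSimParams", function(object) {
    msg <- character()
    if (object@err < 0 || object@err >= 0.25)
        msg <- c(msg, "err must be in [0, 0.25)")
    if (object@readLen < 31L) msg <- c(msg, "readLen must be >= 31")
    if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ReadSimParams", function(object) {
    cat("ReadSimParams |", object@readLen, "bp reads at", object@depth,
        "x | err =", object@err,
        "|", if (object@paired) "paired" else "single", "\n")
})

#' @rdname ReadSimParams-class
#' @param readLen,depth,err,paired,seed See slot documentation.
#' @return A `ReadSimParams` object.
#' @export
readSimParams <- function(readLen = 100L, depth = 15, err = 0.01,
                          paired = FALSE, seed = 1234L) {
    new("ReadSimParams", readLen = as.integer(readLen), depth = depth,
        err = err, paired = paired, seed = as.integer(seed))
}

## Apply i.i.d. substitution errors (never the original base) to a
## character vector of reads, in place.
applyReadErrors <- function(reads, err) {
    if (err <= 0 || !length(reads)) return(reads)
    readLen <- nchar(reads)
    offs <- cumsum(c(0, readLen))
    hit <- which(runif(offs[length(offs)]) < err)
    for (h in hit) {
        i <- findInterval(h - 1L, offs[-length(offs)],
                          rightmost.closed = FALSE)
        pos <- h - offs[i]
        orig <- substr(reads[i], pos, pos)
        substr(reads[i], pos, pos) <- sample(setdiff(DNA_BASES, orig), 1L)
    }
    reads
}

#' Simulate whole-genome-resequencing reads from one haplotype set
#'
#' Uniform start positions, random strand, i.i.d. substitution errors;
#' Phred qualities are a constant placeholder ("I") since nothing
#' downstream uses them. The read count is `round(depth * len /
#' readLen)` (split across haplotypes, and halved into pairs when
#' `paired`). Read names carry the origin
#' (`hap|start0|strand`) so tests can check read provenance.
#'
#' @param sampleSeq Character vector of one or more haplotype
#'   sequences (coverage is divided evenly among them).
#' @param params A [ReadSimParams-class].
#' @return A [Biostrings::DNAStringSet] of reads.
#' @export
simulateWgrReads <- function(sampleSeq, params) {
    stopifnot(is(params, "ReadSimParams"))
    validObject(params)
    if (any(nchar(sampleSeq) < params@readLen))
        stop("readLen exceeds sequence length")
    set.seed(stageSeed(params@seed, "wgr"))
    rl <- params@readLen
    perHapDepth <- params@depth / length(sampleSeq)
    out <- list()
    for (h in seq_along(sampleSeq)) {
        seq <- sampleSeq[h]
        len <- nchar(seq)
        n <- round(perHapDepth * len / rl)
        if (params@paired) n <- max(2L, 2L * (n %/% 2L))
        if (n < 1L) next
        if (params@paired) {
            insert <- 300L
            npair <- n %/% 2L
            start1 <- sample.int(max(1L, len - insert + 1L), npair,
                                 replace = TRUE)
            start2 <- pmin(start1 + insert - rl, len - rl + 1L)
            r1 <- substring(seq, start1, start1 + rl - 1L)
            r2 <- revcompDna(substring(seq, start2, start2 + rl - 1L))
            reads <- as.vector(rbind(r1, r2))
            start0 <- as.vector(rbind(start1, start2)) - 1L
            strand <- rep(c("+", "-"), npair)
        } else {
            start <- sample.int(len - rl + 1L, n, replace = TRUE)
            reads <- substring(seq, start, start + rl - 1L)
            minus <- runif(n) < 0.5
            reads[minus] <- revcompDna(reads[minus])
            start0 <- start - 1L
            strand <- ifelse(minus, "-", "+")
        }
        reads <- applyReadErrors(reads, params@err)
        names(reads) <- sprintf("h%d_r%06d|%d|%s", h, seq_along(reads),
                                start0, strand)
        out[[h]] <- reads
    }
    Biostrings::DNAStringSet(unlist(out, use.names = TRUE))
}

#' Spliced transcript of the chimeric gene
#'
#' Concatenation of the SC1C3 exons on the recombinant haplotype: the
#' CHS1'/CHS3'-containing intron is removed.
#'
#' @param truth A [LocusTruth-class].
#' @return Character scalar.
#' @export
chimericTranscript <- function(truth) {
    gm <- geneModels(truth)
    ex <- gm[gm$gene_id == "SC1C3", ]
    paste(substring(recombinantSeq(truth), ex$start + 1L, ex$end),
          collapse = "")
}

#' Simulate mRNA-seq reads from the spliced chimeric transcript
#'
#' Reads are sampled uniformly from the spliced transcript (exons
#' concatenated, the CHS-containing intron absent), so reads crossing
#' an exon boundary are junction-spanning by construction. Read names
#' record the transcript start position.
#'
#' @param truth A [LocusTruth-class].
#' @param params A [ReadSimParams-class].
#' @return A [Biostrings::DNAStringSet] of reads.
#' @export
simulateMrnaReads <- function(truth, params) {
    stopifnot(is(truth, "LocusTruth"), is(params, "ReadSimParams"))
    if (!nrow(chimericJunctions(truth)))
        stop("truth has no chimeric junctions")
    tx <- chimericTranscript(truth)
    set.seed(stageSeed(params@seed, "mrna"))
    rl <- params@readLen
    len <- nchar(tx)
    n <- round(params@depth * len / rl)
    start <- sample.int(len - rl + 1L, n, replace = TRUE)
    reads <- substring(tx, start, start + rl - 1L)
    minus <- runif(n) < 0.5
    reads[minus] <- revcompDna(reads[minus])
    reads <- applyReadErrors(reads, params@err)
    names(reads) <- sprintf("tx_r%06d|%d|%s", seq_len(n), start - 1L,
                            ifelse(minus, "-", "+"))
    Biostrings::DNAStringSet(reads)
}

#' Simulate small-RNA-seq reads with an appended adapter
#'
#' Primary reads are substrings of the CHS1'/CHS3' hairpin arms inside
#' the chimeric intron (the mirtron-derived population); secondary
#' reads are substrings of CHS paralog exons only, never introns (the
#' phasiRNA population amplified from mature CHS mRNAs). Insert
#' lengths have their mode in 21-24 nt with a minor tail over the rest
#' of 14-43 nt; the 3' adapter is appended to every insert. Read names
#' record class, origin and insert length.
#'
#' @param truth A [LocusTruth-class].
#' @param nPrimary,nSecondary Read counts per class.
#' @param adapter Adapter sequence (>= 8 nt).
#' @param seed Integer seed.
#' @param coreFrac Fraction of inserts drawn from 21-24 nt
#'   (default 0.85); the remainder is uniform over the rest of 14-43.
#' @return A [Biostrings::DNAStringSet] of raw (untrimmed) reads.
#' @export
simulateSmallRnaReads <- function(truth, nPrimary = 4000L,
                                  nSecondary = 4000L,
                                  adapter = "TGGAATTCTCGGGTGCCAAGG",
                                  seed = 1234L, coreFrac = 0.85) {
    stopifnot(is(truth, "LocusTruth"))
    if (nchar(adapter) < 8L) stop("adapter must be >= 8 nt")
    set.seed(stageSeed(seed, "srna"))
    rec <- recombinantSeq(truth)
    reg <- locusRegions(truth)
    arms <- reg[reg$name %in% c("chs1_arm", "chs3_arm"), ]

    drawLen <- function(n) {
        core <- runif(n) < coreFrac
        ifelse(core, sample(21:24, n, replace = TRUE),
               sample(setdiff(14:43, 21:24), n, replace = TRUE))
    }
    drawFrom <- function(regions, n, tag) {
        lens <- drawLen(n)
        ri <- sample(nrow(regions), n, replace = TRUE,
                     prob = regions$end - regions$start)
        lo <- regions$start[ri]
        hi <- regions$end[ri] - lens
        start0 <- lo + floor(runif(n) * (hi - lo + 1L))
        ins <- substring(rec, start0 + 1L, start0 + lens)
        minus <- runif(n) < 0.5
        ins[minus] <- revcompDna(ins[minus])
        names(ins) <- sprintf("%s_r%06d|%s|%d|%d", tag, seq_len(n),
                              regions$name[ri], start0, lens)
        ins
    }

    primary <- drawFrom(arms, nPrimary, "pri")

    gm <- geneModels(truth)
    ex <- gm[gm$contig == "recombinant" &
             gm$gene_id %in% c("CHS1p", "CHS3p", "CHS4p", "CHS7p"), ]
    exRegions <- data.frame(name = paste0(ex$gene_id, "_exon"),
                            start = ex$start, end = ex$end)
    secondary <- drawFrom(exRegions, nSecondary, "sec")

    inserts <- c(primary, secondary)
    raw <- paste0(inserts, adapter)
    names(raw) <- names(inserts)
    Biostrings::DNAStringSet(raw)
}
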