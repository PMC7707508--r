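ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter detection recovers a planted adapter and refuses noise", {
    tr <- small_truth()
    idx12 <- buildReferenceIndex(
        c(ancestral = ancestralSeq(tr),
          recombinant = recombinantSeq(tr)), k = 12L)
    raw <- simulateSmallRnaReads(tr, 400L, 400L, adapter = ADAPTER,
                                 seed = 71L)
    call <- detectAdapter(raw, idx12)
    expect_true(call@found)
    ## detected sequence is prefix-consistent with the planted adapter
    expect_true(startsWith(ADAPTER, call@adapter) ||
                startsWith(call@adapter, ADAPTER))
    expect_gte(call@fraction, 0.2)
    ## adapter-free reads drawn from the reference: not found
    set.seed(72)
    starts <- sample(2000, 300)
    genomic <- substring(ancestralSeq(tr), starts, starts + 49)
    expect_false(detectAdapter(genomic, idx12)@found)
})

test_that("adapter trimming cuts at the leading 8-mer and length-filters", {
    set.seed(73)
    ins21 <- random_dna(21)
    r <- trimAdapter(paste0(ins21, ADAPTER), ADAPTER)
    expect_equal(unname(r$reads), ins21)
    ## a 50 nt read with no adapter occurrence exceeds 43: discarded
    r2 <- trimAdapter(random_dna(50), ADAPTER)
    expect_length(r2$reads, 0L)
    expect_equal(r2$nLong, 1L)
    expect_equal(r2$nNoAdapter, 1L)
    ## a 13 nt insert falls below 14: discarded
    r3 <- trimAdapter(paste0(random_dna(13), ADAPTER), ADAPTER)
    expect_length(r3$reads, 0L)
    expect_equal(r3$nShort, 1L)
})

test_that("exact mapping reports all and only perfect occurrences", {
    tr <- small_truth(seed = 74L, chs13Identity = 1.0)
    rec <- recombinantSeq(tr)
    reg <- locusRegions(tr)
    ## a unique substring: exactly one hit at its position
    rd <- substring(rec, 501, 522)
    aln <- mapReadsExact(c(u = rd), c(recombinant = rec))
    expect_equal(nrow(aln), 1L)
    expect_equal(aln$start, 500L)
    expect_equal(aln$strand, "+")
    ## a read from the identical-arm core hits both arms on opposite
    ## strands
    a1 <- reg[reg$name == "chs1_arm", ]
    core <- substring(rec, a1$start + 701L, a1$start + 722L)
    aln2 <- mapReadsExact(c(core = core), c(recombinant = rec))
    expect_equal(nrow(aln2), 2L)
    expect_setequal(aln2$strand, c("+", "-"))
    ## one substitution: unmapped under the no-mismatch contract
    bad <- rd
    substr(bad, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                 substring(bad, 5, 5))[1]
    expect_equal(nrow(mapReadsExact(c(b = bad), c(recombinant = rec))), 0L)
    ## strand symmetry: mapping against the reverse-complemented
    ## reference yields the same number of hits
    alnRC <- mapReadsExact(c(core = core),
                           c(recombinant = oracle_revcomp(rec)))
    expect_equal(nrow(alnRC), nrow(aln2))
})

test_that("junction-read counting applies anchors and the coverage bar", {
    tr <- small_truth()
    cj <- chimericJunctions(tr)
    ## zero reads: all counts 0, nothing passes
    j0 <- countJunctionReads(character(), recombinantSeq(tr), cj)
    expect_true(all(j0$count == 0L))
    expect_false(any(j0$passes_min))
    ## depth-50 mRNA: the subtilisin-exon4 -> novel-exon junction
    ## clears minimum coverage 5
    mr <- simulateMrnaReads(tr, readSimParams(depth = 50, err = 0,
                                              seed = 75L))
    jc <- countJunctionReads(mr, recombinantSeq(tr), cj)
    expect_true(all(jc$passes_min))
    fusion <- jc[jc$acceptor_start ==
                 max(cj$acceptor_start), ]
    expect_gte(fusion$count, 5L)
    ## reads from the unspliced pre-mRNA never span a junction
    set.seed(76)
    gspan <- locusRegions(tr)[locusRegions(tr)$name == "chimeric_gene", ]
    starts <- sample(gspan$start:(gspan$end - 100), 300) + 1L
    pre <- substring(recombinantSeq(tr), starts, starts + 99)
    jpre <- countJunctionReads(pre, recombinantSeq(tr), cj)
    expect_true(all(jpre$count == 0L))
    ## a read shorter than the anchor is rejected
    expect_error(countJunctionReads("ACGTT", recombinantSeq(tr), cj,
                                    anchor = 8L), "anchor")
})

test_that("a junction read needs the full anchor on both sides", {
    ## hand-built gene: two exons around a removed intron
    contig <- paste0("AAAACCCCGGGGTTTT", "ACGTACGTACGTACGTACGT",
                     "TTTTGGGGCCCCAAAA")
    ## exon1 = [0,16), intron = [16,36), exon2 = [36,52)
    jct <- data.frame(donor_end = 16L, acceptor_start = 36L)
    spliced <- paste0(substr(contig, 1, 16), substr(contig, 37, 52))
    ok <- substr(spliced, 9, 24)       # 8 bases each side
    short <- substr(spliced, 10, 24)   # 7 donor bases only
    res <- countJunctionReads(c(ok, short), contig, jct, anchor = 8L,
                              minCoverage = 1L)
    expect_equal(res$count, 1L)
})

test_that("small-RNA profiles partition reads by exon/intron placement", {
    gm <- geneModel("g", "chr", "+", starts = c(100L, 400L),
                    ends = c(200L, 500L))
    ## all reads inside exon 1: intronic fraction 0
    alnE <- data.frame(read = "r", contig = "chr",
                       start = seq(110L, 160L, by = 10L), width = 21L,
                       strand = "+")
    profE <- profileSmallRna(alnE, gm)
    expect_equal(intronicFraction(profE), 0)
    ## all reads inside the intron: fraction 1
    alnI <- data.frame(read = "r", contig = "chr",
                       start = seq(210L, 360L, by = 10L), width = 21L,
                       strand = "+")
    profI <- profileSmallRna(alnI, gm)
    expect_equal(intronicFraction(profI), 1)
    ## straddling reads are excluded from the fraction
    alnS <- data.frame(read = "r", contig = "chr",
                       start = c(110L, 250L, 190L), width = 21L,
                       strand = "+")
    profS <- profileSmallRna(alnS, gm)
    expect_equal(profS@straddleReads, 1L)
    expect_equal(intronicFraction(profS), 0.5)
    ## depth conservation over contained reads
    expect_equal(sum(profE@depth), 6 * 21)
})

test_that("the mirtron signature separates the chimeric gene from paralogs", {
    tr <- small_truth()
    raw <- simulateSmallRnaReads(tr, 1200L, 1200L, adapter = ADAPTER,
                                 seed = 77L)
    trm <- trimAdapter(raw, ADAPTER)
    aln <- mapReadsExact(trm$reads,
                         c(recombinant = recombinantSeq(tr)))
    gms <- truthGeneModels(tr, "recombinant")
    fr <- vapply(gms[c("SC1C3", "CHS4p", "CHS7p")],
                 function(g) intronicFraction(profileSmallRna(aln, g)),
                 numeric(1))
    expect_gt(fr[["SC1C3"]], 0.3)
    expect_equal(unname(fr[c("CHS4p", "CHS7p")]), c(0, 0))
})

test_that("perfect-match coverage equals the brute-force window scan", {
    set.seed(78)
    ## identity
    a <- random_dna(400)
    expect_equal(paralogPerfectMatchCoverage(a, a)@fraction, 1.0)
    ## no shared 20-mer between independent random sequences
    b <- random_dna(400)
    expect_equal(paralogPerfectMatchCoverage(a, b)@fraction, 0.0)
    ## a planted 120 bp exact copy inside 1000 bp: 120 covered, 0.12
    donor <- substring(a, 101, 220)
    subj <- paste0(random_dna(500), donor, random_dna(380))
    rep1 <- paralogPerfectMatchCoverage(a, subj)
    expect_equal(rep1@coveredBp, 120L)
    expect_equal(rep1@fraction, 0.12)
    ## reverse-orientation copies are found too
    subjRC <- paste0(random_dna(300), oracle_revcomp(donor),
                     random_dna(580))
    expect_equal(paralogPerfectMatchCoverage(a, subjRC)@coveredBp, 120L)
    ## oracle: position-by-position window scan on mutated paralogs
    for (i in 1:3) {
        q <- random_dna(600)
        s <- q
        hits <- sample(600, 35)
        for (p in hits)
            substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substring(s, p, p)), 1)
        got <- paralogPerfectMatchCoverage(q, s, minLen = 20L)
        wins <- vapply(1:(600 - 19), function(j)
            oracle_occurs(substring(s, j, j + 19), q), logical(1))
        cov <- logical(600)
        for (j in which(wins)) cov[j:(j + 19)] <- TRUE
        expect_equal(got@coveredBp, sum(cov))
    }
})
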