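test_that("degenerate WGR simulation returns the sequence itself", {
    set.seed(41)
    src <- random_dna(200)
    reads <- simulateWgrReads(src, readSimParams(readLen = 200L,
                                                 depth = 1, err = 0,
                                                 seed = 1L))
    expect_length(reads, 1L)
    rd <- as.character(reads[[1]])
    expect_true(rd == src || rd == oracle_revcomp(src))
    expect_error(
        simulateWgrReads(random_dna(50),
                         readSimParams(readLen = 100L, seed = 1L)),
        "exceeds")
})

test_that("read count follows depth x length / readLen", {
    set.seed(42)
    src <- random_dna(50000)
    reads <- simulateWgrReads(src, readSimParams(depth = 15, err = 0,
                                                 seed = 2L))
    expect_length(reads, 7500L)  # round(15 * 50000 / 100)
    ## conservation: simulated bases = n_reads x read_len
    expect_equal(sum(Biostrings::width(reads)), 7500L * 100L)
    prs <- simulateWgrReads(src, readSimParams(depth = 15, err = 0,
                                               paired = TRUE, seed = 2L))
    expect_length(prs, 7500L)  # 3750 pairs
})

test_that("substitution errors hit at the requested rate", {
    set.seed(43)
    src <- random_dna(50000)
    reads <- simulateWgrReads(src, readSimParams(depth = 20, err = 0.01,
                                                 seed = 3L))
    ## 10^6 simulated bases; recover each read's origin from its name
    ## and count mismatches against the source
    meta <- strsplit(names(reads), "|", fixed = TRUE)
    start0 <- as.integer(vapply(meta, `[`, character(1), 2L))
    strand <- vapply(meta, `[`, character(1), 3L)
    rd <- as.character(reads)
    rd[strand == "-"] <- oracle_revcomp(rd[strand == "-"])
    truth <- substring(src, start0 + 1L, start0 + 100L)
    mm <- sum(vapply(seq_along(rd), function(i) {
        sum(strsplit(rd[i], "")[[1]] != strsplit(truth[i], "")[[1]])
    }, numeric(1)))
    frac <- mm / (length(rd) * 100)
    expect_gte(frac, 0.008)
    expect_lte(frac, 0.012)
})

test_that("mRNA reads come from the spliced transcript only", {
    tr <- small_truth()
    tx <- chimericTranscript(tr)
    reads <- simulateMrnaReads(tr, readSimParams(depth = 20, err = 0,
                                                 seed = 4L))
    ## every error-free read maps exactly to the spliced transcript
    ## (hence zero reads from the removed intron)
    for (rd in as.character(reads))
        expect_true(oracle_occurs(rd, tx))
    ## and the intron interval truly is absent from the transcript
    reg <- locusRegions(tr)
    intr <- reg[reg$name == "chimeric_intron", ]
    intronSeq <- substring(recombinantSeq(tr), intr$start + 1L, intr$end)
    probe <- substring(intronSeq, 300, 360)
    expect_false(oracle_occurs(probe, tx))
})

test_that("small-RNA reads respect their class origins and length law", {
    tr <- small_truth()
    adapter <- "TGGAATTCTCGGGTGCCAAGG"
    raw <- simulateSmallRnaReads(tr, nPrimary = 800L, nSecondary = 800L,
                                 adapter = adapter, seed = 5L)
    meta <- strsplit(names(raw), "|", fixed = TRUE)
    origin <- vapply(meta, `[`, character(1), 2L)
    start0 <- as.integer(vapply(meta, `[`, character(1), 3L))
    len <- as.integer(vapply(meta, `[`, character(1), 4L))
    ## raw read = insert + adapter
    expect_equal(unique(Biostrings::width(raw) - len), nchar(adapter))
    ## primary reads originate inside the hairpin arms
    reg <- locusRegions(tr)
    pri <- grepl("^pri", names(raw))
    for (arm in c("chs1_arm", "chs3_arm")) {
        a <- reg[reg$name == arm, ]
        inArm <- origin == arm
        expect_true(all(start0[inArm] >= a$start &
                        start0[inArm] + len[inArm] <= a$end))
    }
    expect_true(all(origin[pri] %in% c("chs1_arm", "chs3_arm")))
    ## secondary reads originate inside paralog exons, never introns
    gm <- geneModels(tr)
    sec <- !pri
    ok <- vapply(which(sec), function(i) {
        ex <- gm[paste0(gm$gene_id, "_exon") == origin[i] &
                 gm$contig == "recombinant", ]
        any(start0[i] >= ex$start & start0[i] + len[i] <= ex$end)
    }, logical(1))
    expect_true(all(ok))
    ## insert length range and mode
    expect_true(all(len >= 14 & len <= 43))
    expect_true(as.integer(names(which.max(table(len)))) %in% 21:24)
})

test_that("identical seeds give byte-identical FASTQ output", {
    tr <- small_truth()
    f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
    r1 <- simulateWgrReads(ancestralSeq(tr),
                           readSimParams(depth = 2, seed = 9L))
    r2 <- simulateWgrReads(ancestralSeq(tr),
                           readSimParams(depth = 2, seed = 9L))
    writeFastqFile(r1, f1); writeFastqFile(r2, f2)
    expect_identical(readLines(f1), readLines(f2))
    s1 <- simulateSmallRnaReads(tr, 50L, 50L, seed = 10L)
    s2 <- simulateSmallRnaReads(tr, 50L, 50L, seed = 10L)
    expect_identical(as.character(s1), as.character(s2))
})
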