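test_that("reference index enumerates every canonical k-mer position", {
    set.seed(61)
    c31 <- random_dna(31)
    idx1 <- buildReferenceIndex(c(chr = c31), k = 31L)
    expect_equal(nrow(idx1@table), 1L)
    expect_equal(idx1@table$kmer, oracle_canonical(c31))
    expect_equal(idx1@table$offset, 0L)
    ## a contig plus its reverse complement: every key gets >= 2 hits
    ctg <- random_dna(300)
    idx2 <- buildReferenceIndex(c(fwd = ctg, rev = oracle_revcomp(ctg)),
                                k = 31L)
    perKey <- table(idx2@table$kmer)
    expect_true(all(perKey >= 2))
    ## key set equals the brute-force canonical k-mer set
    expect_setequal(unique(idx2@table$kmer),
                    names(oracle_kmer_count(c(ctg, oracle_revcomp(ctg)),
                                            31L)))
    ## every recorded position reproduces its k-mer when sliced
    for (i in sample(nrow(idx2@table), 20)) {
        h <- idx2@table[i]
        sliced <- substring(if (h$contig == "fwd") ctg else
                            oracle_revcomp(ctg),
                            h$offset + 1L, h$offset + 31L)
        if (h$strand == "-") sliced <- oracle_revcomp(sliced)
        expect_equal(sliced, h$kmer)
    }
})

test_that("anchoring localizes reference k-mers and flags junction ones", {
    tr <- small_truth()
    idxA <- buildReferenceIndex(c(ancestral = ancestralSeq(tr)),
                                name = "ancestral")
    idxR <- buildReferenceIndex(c(recombinant = recombinantSeq(tr)),
                                name = "recombinant")
    ## a k-mer sliced from the ancestral sequence anchors at its slice
    sliced <- substring(ancestralSeq(tr), 1001, 1031)
    hit <- anchorKmer(sliced, idxA)
    expect_true(hit@anchored)
    expect_true(1000L %in% hit@hits$offset)
    ## junction k-mers: unanchored on ancestral, anchored on the
    ## recombinant only
    jk <- junctionKmers(tr)[1]
    expect_false(anchorKmer(jk, idxA)@anchored)
    both <- anchorKmer(jk, list(idxA, idxR))
    expect_true(both@anchored)
    expect_setequal(both@hits$reference, "recombinant")
    expect_error(anchorKmer("ACGT", idxA), "length")
})

test_that("palindromic placements report all positions and strands", {
    set.seed(62)
    w <- random_dna(31)
    ctg <- paste0(random_dna(40), w, random_dna(40), oracle_revcomp(w),
                  random_dna(40))
    idx <- buildReferenceIndex(c(chr = ctg), k = 31L)
    hit <- anchorKmer(w, idx)
    expect_equal(nrow(hit@hits), 2L)
    expect_setequal(hit@hits$strand, c("+", "-"))
    expect_setequal(hit@hits$offset, c(40L, 111L))
})

test_that("significant k-mers partition into anchored and unanchored", {
    tr <- small_truth()
    idxA <- buildReferenceIndex(c(ancestral = ancestralSeq(tr)),
                                name = "ancestral")
    idxR <- buildReferenceIndex(c(recombinant = recombinantSeq(tr)),
                                name = "recombinant")
    jk <- junctionKmers(tr)
    anc <- substring(ancestralSeq(tr), c(501, 1501), c(531, 1531))
    km <- sort(canonicalizeKmer(c(jk[1:3], anc)))
    rec <- data.frame(kmer = km, a = 10L, b = 0L, c = 0L, d = 10L,
                      chi2 = 20, p = 1e-6, fisher_p = NA_real_,
                      odds_ratio = 441, significant = TRUE)
    res <- new("GwasResult", records = rec,
               binarization = new("Binarization", trait = "hilum",
                                  caseCategories = "colorless",
                                  controlCategories = "black",
                                  caseSamples = "a", controlSamples = "b"),
               mTests = 5L, alpha = 0.05, threshold = 1e-5)
    cls <- classifySignificantKmers(res, idxA)
    expect_setequal(cls$unanchored$kmer, canonicalizeKmer(jk[1:3]))
    expect_setequal(cls$anchored$kmer, canonicalizeKmer(anc))
    ## with the full (ancestral + recombinant) reference nothing is
    ## unanchored
    cls2 <- classifySignificantKmers(res, list(idxA, idxR))
    expect_equal(nrow(cls2$unanchored), 0L)
})

test_that("site k-mer pairs are complete, disjoint and skip crowded sites", {
    tr <- small_truth()
    sites <- snpSites(tr)
    pairs <- buildSiteKmerPairs(ancestralSeq(tr), sites, k = 31L)
    expect_length(pairs, nrow(sites))
    for (pr in pairs[1:5]) {
        expect_lte(length(pr$refKmers), 31L)
        expect_equal(length(pr$refKmers), length(pr$altKmers))
        expect_length(intersect(pr$refKmers, pr$altKmers), 0L)
    }
    ## two sites inside one k-window are both skipped
    crowded <- data.frame(pos = c(100L, 110L),
                          ref = substring(ancestralSeq(tr),
                                          c(101, 111), c(101, 111)),
                          alt = c("A", "A"))
    crowded$alt <- ifelse(crowded$ref == "A", "C", "A")
    expect_length(buildSiteKmerPairs(ancestralSeq(tr), crowded), 0L)
})

test_that("genotype calls follow the ref/alt k-mer presence rule", {
    tr <- small_truth()
    pairs <- buildSiteKmerPairs(ancestralSeq(tr), snpSites(tr))
    ## an error-free homozygous-reference sample: ref/ref everywhere
    refSet <- make_set(names(oracle_kmer_count(ancestralSeq(tr), 31L)),
                       "ref")
    expect_true(all(inferSiteGenotypesFromKmers(pairs, refSet) == "0/0"))
    ## constructed sample with one ref and one alt k-mer at site 1: het
    p1 <- pairs[[1]]
    hetSet <- make_set(c(p1$refKmers[1], p1$altKmers[1]), "het")
    calls <- inferSiteGenotypesFromKmers(pairs, hetSet)
    expect_equal(unname(calls[1]), "0/1")
    ## all other sites have no evidence: missing
    expect_true(all(calls[-1] == "missing"))
})

test_that("concordance arithmetic and error handling are exact", {
    gt <- matrix(rep(c("0/0", "0/1", "1/1", "0/0"), 50), nrow = 10,
                 dimnames = list(sprintf("site%02d", 1:10),
                                 sprintf("s%02d", 1:20)))
    expect_equal(genotypeConcordance(gt, gt)@percent, 100)
    gt2 <- gt
    gt2[1, 1] <- "1/1"
    expect_equal(genotypeConcordance(gt, gt2)@percent, 100 * 199 / 200)
    ## missing genotypes are excluded from the denominator
    gt3 <- gt
    gt3[1, ] <- "missing"
    rep3 <- genotypeConcordance(gt3, gt2)
    expect_equal(rep3@nGenotypes, 180L)
    ## zero comparable genotypes is an error, not 0%
    allMiss <- gt
    allMiss[] <- "missing"
    expect_error(genotypeConcordance(allMiss, gt), "zero comparable")
})

test_that("concordance does not improve as read error grows", {
    tr <- small_truth()
    co <- simulateCohort(cohortSpec(nAccessions = 8L, seed = 63L), tr)
    pairs <- buildSiteKmerPairs(ancestralSeq(tr), snpSites(tr))
    conc <- vapply(c(0, 0.01, 0.02), function(e) {
        sets <- cohortKmerSets(tr, co, readSimParams(err = e, seed = 64L))
        genotypeConcordance(inferCohortGenotypes(pairs, sets),
                            snpGenotypes(co))@percent
    }, numeric(1))
    expect_equal(conc[1], 100)
    expect_true(all(diff(conc) <= 0))
})
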