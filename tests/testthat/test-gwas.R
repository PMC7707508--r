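random_kmers <- function(n, k = 31L) {
    unique(vapply(seq_len(n), function(i) oracle_canonical(random_dna(k)),
                  character(1)))
}

test_that("presence matrix applies the polymorphism band correctly", {
    set.seed(51)
    km <- random_kmers(12)
    shared <- km[1:4]; rare <- km[5]; mid <- km[6]
    ## 3 samples all containing the shared k-mers: monomorphic, removed
    sets <- list(make_set(c(shared, mid), "s1"),
                 make_set(shared, "s2"),
                 make_set(c(shared, rare), "s3"))
    mat <- buildPresenceMatrix(sets)
    expect_false(any(shared %in% kmers(mat)))
    ## frequency 1/3 and 2/3 rows survive
    expect_setequal(kmers(mat), sort(c(rare, mid)))
    ## boundary: presence 1/20 = 0.05 is not < 0.05, so retained
    sets20 <- c(list(make_set(c(km[7], km[8]), "t01")),
                lapply(2:20, function(i)
                    make_set(km[8], sprintf("t%02d", i))))
    mat20 <- buildPresenceMatrix(sets20)
    expect_true(km[7] %in% kmers(mat20))    # freq 0.05 kept
    expect_false(km[8] %in% kmers(mat20))   # freq 1 removed
    ## mismatched k across samples is an error
    expect_error(buildPresenceMatrix(list(make_set("ACGTA"),
                                          make_set(km[1], "x"))),
                 "same k")
})

test_that("pseudo-VCF encoding round-trips through a standard parser", {
    set.seed(52)
    km <- sort(random_kmers(6))
    sets <- list(make_set(km[c(1, 2, 3)], "sampleA"),
                 make_set(km[c(2, 4)], "sampleB"),
                 make_set(km[c(3, 4)], "sampleC"))
    mat <- buildPresenceMatrix(sets)
    vcf <- tempfile(fileext = ".vcf")
    writePseudoVcf(mat, vcf)
    lines <- readLines(vcf)
    body <- lines[!startsWith(lines, "#")]
    ## record count equals retained row count
    expect_length(body, length(kmers(mat)))
    ## genotype encoding: "1/1" present, "0/0" absent, POS = rank
    f1 <- strsplit(body[1], "\t")[[1]]
    expect_equal(f1[1:5], c("KMERS", "1", kmers(mat)[1], "A", "T"))
    expect_equal(f1[10:12],
                 ifelse(presence(mat)[1, ], "1/1", "0/0"))
    ## parse-then-rebuild equals the original matrix
    back <- readPseudoVcf(vcf)
    expect_equal(kmers(back), kmers(mat))
    expect_equal(sampleIds(back), sampleIds(mat))
    expect_equal(presence(back), presence(mat))
    expect_equal(kmerLength(back), kmerLength(mat))
})

test_that("binarization enumeration yields 2^(c-1) - 1 bipartitions", {
    traits <- data.frame(
        accession_id = sprintf("a%02d", 1:12),
        pheno = rep(c("A", "B", "C", "D"), 3))
    for (cc in 2:4) {
        sub <- traits[traits$pheno %in% LETTERS[1:cc], ]
        bins <- enumerateBinarizations(sub, "pheno")
        expect_length(bins, 2^(cc - 1) - 1)
    }
    ## c = 3: the three bipartitions are {A|BC}, {B|AC}, {C|AB}
    sub3 <- traits[traits$pheno %in% c("A", "B", "C"), ]
    bins3 <- enumerateBinarizations(sub3, "pheno")
    parts <- lapply(bins3, function(b)
        paste(sort(b@caseCategories), collapse = ""))
    expect_setequal(unlist(lapply(parts, function(p)
        if (nchar(p) == 1) p else setdiff(c("A", "B", "C"),
                                          strsplit(p, "")[[1]]))),
        c("A", "B", "C"))
    ## samples with missing labels are excluded from both sides
    traitsNA <- traits
    traitsNA$pheno[1] <- NA
    bNA <- binarizeTrait(traitsNA, "pheno", "A")
    expect_false("a01" %in% c(bNA@caseSamples, bNA@controlSamples))
})

test_that("allelic chi-squared matches closed forms and degenerates", {
    ## proportional table: no association
    res <- allelicAssociation(6, 18, 2, 6)
    expect_equal(res$chi2, 0)
    expect_equal(res$p, 1)
    ## balanced perfect separation: chi2 = n
    res <- allelicAssociation(10, 0, 0, 10)
    expect_equal(res$chi2, 20)
    ## degenerate column margin
    res <- allelicAssociation(0, 5, 0, 5)
    expect_equal(res$chi2, 0)
    expect_equal(res$p, 1)
    expect_error(allelicAssociation(-1, 5, 2, 3), "nonnegative")
    expect_error(allelicAssociation(0, 0, 2, 3), ">= 1")
})

test_that("case/control label swap leaves chi2 and p unchanged", {
    set.seed(53)
    for (i in 1:25) {
        x <- sample(0:30, 4, replace = TRUE) + c(1, 0, 1, 0)
        a <- allelicAssociation(x[1], x[2], x[3], x[4])
        b <- allelicAssociation(x[3], x[4], x[1], x[2])
        expect_equal(a$chi2, b$chi2)
        expect_equal(a$p, b$p)
        if (all(x > 0))  # odds ratio inverts where defined without
            expect_equal(a$odds_ratio, 1 / b$odds_ratio)
    }
})

test_that("chi-squared and Fisher p agree with the stats oracles", {
    set.seed(54)
    for (i in 1:100) {
        x <- sample(1:25, 4, replace = TRUE)  # all margins positive
        got <- allelicAssociation(x[1], x[2], x[3], x[4])
        ora <- suppressWarnings(chisq.test(
            matrix(x, 2, byrow = TRUE), correct = FALSE))
        expect_equal(got$chi2, unname(ora$statistic), tolerance = 1e-12)
        expect_equal(got$p, ora$p.value, tolerance = 1e-12)
        fo <- fisher.test(matrix(x, 2, byrow = TRUE))
        expect_equal(fisherExactP(x[1], x[2], x[3], x[4]), fo$p.value,
                     tolerance = 1e-9)
    }
})

test_that("GWAS ranks a perfectly separating k-mer first", {
    set.seed(55)
    km <- random_kmers(60)
    causal <- km[1]; noise <- km[2:50]
    ids <- sprintf("s%02d", 1:60)
    case <- ids[1:30]
    pres <- matrix(runif(49 * 60) < 0.5, nrow = 49,
                   dimnames = list(noise, ids))
    pres <- rbind(matrix(ids %in% case, nrow = 1,
                         dimnames = list(causal, NULL)), pres)
    mat <- presenceMatrix(pres)
    traits <- data.frame(accession_id = ids,
                         hilum = ifelse(ids %in% case, "colorless",
                                        "black"))
    bin <- binarizeTrait(traits, "hilum", "colorless")
    res <- runKmerGwas(mat, bin)
    expect_equal(records(res)$kmer[1], causal)
    expect_true(records(res)$significant[1])
    ## mTests = retained rows, threshold = alpha / mTests
    expect_equal(res@mTests, length(kmers(mat)))
    expect_equal(significanceThreshold(res), 0.05 / length(kmers(mat)))
    ## fixed override wins
    res9 <- runKmerGwas(mat, bin, fixedThreshold = 5e-9)
    expect_equal(significanceThreshold(res9), 5e-9)
    ## sample order is irrelevant
    perm <- sample(ncol(pres))
    matP <- presenceMatrix(pres[, perm], k = 31L)
    resP <- runKmerGwas(matP, bin)
    expect_equal(records(resP), records(res))
    ## empty side after intersection errors
    binBad <- new("Binarization", trait = "hilum",
                  caseCategories = "x", controlCategories = "y",
                  caseSamples = "zz1", controlSamples = ids[1])
    expect_error(runKmerGwas(mat, binBad), "empty")
})

test_that("locus spans reproduce the published kbp arithmetic", {
    expect_equal(locusSpanKbp(53087195, 53269307), 182L)
    expect_equal(locusSpanKbp(17683675, 19248187), 1565L)
    expect_equal(locusSpanKbp(8360663, 8622831), 262L)
    expect_equal(locusSpanKbp(45576015, 45939643), 364L)
    expect_equal(locusSpanKbp(100, 1100), 1L)
    expect_error(locusSpanKbp(10, 10), "end")
})
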