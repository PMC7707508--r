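## Memoized fixtures. The heavy default-scale cohort run is built once
## per test session and shared by the tests that need it.

.fixtures <- new.env(parent = emptyenv())

## Small locus pair for unit tests (desk-scale sequences).
small_truth <- function(seed = 1234L, ...) {
    key <- paste0("truth_", seed, "_", paste(c(...), collapse = "_"))
    if (is.null(.fixtures[[key]]))
        .fixtures[[key]] <- buildLocusPair(
            locusBlueprint(flankLen = 2500L, seed = seed, ...))
    .fixtures[[key]]
}

## Full default-scale study: ~50 kb locus, 60 accessions, 15x reads at
## err = 0.01, hilum association, ancestral-only anchoring, and
## k-mer-derived genotype concordance.
default_run <- function() {
    if (!is.null(.fixtures$run)) return(.fixtures$run)
    truth <- buildLocusPair(locusBlueprint(seed = 1234L))
    cohort <- simulateCohort(cohortSpec(seed = 1234L), truth)
    sets <- cohortKmerSets(truth, cohort,
                           readSimParams(err = 0.01, seed = 1234L))
    mat <- buildPresenceMatrix(sets)
    bin <- binarizeTrait(traitTable(cohort), "hilum", "colorless")
    res <- runKmerGwas(mat, bin)
    idxA <- buildReferenceIndex(c(ancestral = ancestralSeq(truth)),
                                name = "ancestral")
    cls <- classifySignificantKmers(res, idxA)
    pairs <- buildSiteKmerPairs(ancestralSeq(truth), snpSites(truth))
    calls <- inferCohortGenotypes(pairs, sets)
    conc <- genotypeConcordance(calls, snpGenotypes(cohort))
    .fixtures$run <- list(truth = truth, cohort = cohort, sets = sets,
                          mat = mat, bin = bin, res = res, idxA = idxA,
                          cls = cls, pairs = pairs, conc = conc)
    .fixtures$run
}

## The same cohort re-sequenced without errors (concordance must be
## perfect).
default_run_err0 <- function() {
    if (!is.null(.fixtures$run0)) return(.fixtures$run0)
    run <- default_run()
    sets0 <- cohortKmerSets(run$truth, run$cohort,
                            readSimParams(err = 0, seed = 1234L))
    calls0 <- inferCohortGenotypes(run$pairs, sets0)
    conc0 <- genotypeConcordance(calls0, snpGenotypes(run$cohort))
    .fixtures$run0 <- list(sets = sets0, conc = conc0)
    .fixtures$run0
}

## Tiny sample k-mer set built directly from a character vector.
make_set <- function(kmers, id = "s", k = nchar(kmers[1])) {
    new("SampleKmerSet", sampleId = id, k = as.integer(k),
        kmers = sort(unique(kmers), method = "radix"),
        nRaw = as.numeric(length(kmers)))
}
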