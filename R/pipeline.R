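#' Per-sample k-mer sets for a simulated cohort
#'
#' For each accession: build its two haplotype sequences, simulate
#' whole-genome-resequencing reads, count canonical k-mers and apply
#' the singleton filter. Per-sample read streams get distinct seeds
#' derived from `params@seed`, so the whole cohort is reproducible
#' from one integer.
#'
#' @param truth A [LocusTruth-class].
#' @param cohort A [Cohort-class].
#' @param params A [ReadSimParams-class]; `params@seed` is the base
#'   seed fanned out per sample.
#' @param k K-mer length.
#' @param minCount Singleton filter (default 2).
#' @return Named list of [SampleKmerSet-class].
#' @export
cohortKmerSets <- function(truth, cohort, params, k = 31L,
                           minCount = 2L) {
    stopifnot(is(truth, "LocusTruth"), is(cohort, "Cohort"),
              is(params, "ReadSimParams"))
    ids <- sampleIds(cohort)
    gts <- snpGenotypes(cohort)
    al <- alleles(cohort)
    out <- vector("list", length(ids))
    names(out) <- ids
    for (i in seq_along(ids)) {
        haps <- sampleHaplotypes(truth, al[i], gts[, i])
        p <- new("ReadSimParams", readLen = params@readLen,
                 depth = params@depth, err = params@err,
                 paired = params@paired,
                 seed = as.integer((params@seed + 13L * i) %% 2147483647))
        reads <- simulateWgrReads(haps, p)
        out[[i]] <- sampleKmerSet(reads, k = k, minCount = minCount,
                                  sampleId = ids[i])
    }
    out
}

#' K-mer-derived genotype matrix for a cohort
#'
#' Applies [inferSiteGenotypesFromKmers()] to every sample set.
#'
#' @param pairs Output of [buildSiteKmerPairs()].
#' @param sets List of [SampleKmerSet-class] (one per sample).
#' @return Character matrix sites x samples.
#' @export
inferCohortGenotypes <- function(pairs, sets) {
    calls <- vapply(sets, function(s) inferSiteGenotypesFromKmers(pairs, s),
                    character(length(pairs)))
    colnames(calls) <- vapply(sets, sampleId, character(1))
    calls
}
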