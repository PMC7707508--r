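#' Specification of a synthetic accession cohort
#'
#' Defaults emulate the study conditions the pipeline is built for: an
#' inbred cohort segregating the recombinant I-locus haplotype, with
#' the colorless-hilum phenotype linked to the recombinant allele at
#' high but incomplete penetrance (0.95) and a small phenocopy leak
#' (0.013, matching the 1.3 percent presence of the junction k-mer in
#' the contrasting colored-hilum subpopulation).
#'
#' @param nAccessions Cohort size (default 60).
#' @param recombAlleleFreq Recombinant-haplotype frequency (default 0.3).
#' @param penetrance P(colorless hilum | recombinant allele).
#' @param leak P(colorless hilum | ancestral allele).
#' @param categories Named list of trait category labels; must contain
#'   seed_coat, hilum (with a "colorless" category) and pubescence.
#' @param inbreeding Inbreeding coefficient F for SNP genotypes.
#'   Default 1: accessions are pure selfing lines, so every genotype
#'   is homozygous; lower values introduce residual heterozygosity.
#' @param seed Integer seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nAccessions = 60L,
                       recombAlleleFreq = 0.3,
                       penetrance = 0.95,
                       leak = 0.013,
                       categories = list(
                           seed_coat = c("black", "brown", "yellow",
                                         "green"),
                           hilum = c("black", "brown", "colorless"),
                           pubescence = c("tawny", "gray", "brown")),
                       inbreeding = 1,
                       seed = 1234L) {
    if (!"colorless" %in% categories$hilum)
        stop("hilum categories must include 'colorless'")
    new("CohortSpec", nAccessions = as.integer(nAccessions),
        recombAlleleFreq = recombAlleleFreq, penetrance = penetrance,
        leak = leak, categories = categories, inbreeding = inbreeding,
        seed = as.integer(seed))
}

#' Simulate a cohort over a locus truth
#'
#' Locus alleles are drawn i.i.d. at the recombinant-allele frequency
#' (homozygous: accessions are inbred). The hilum label is "colorless"
#' with probability `penetrance` for carriers and `leak` for
#' non-carriers; otherwise a non-colorless hilum category is drawn
#' uniformly. Seed-coat and pubescence labels are drawn uniformly and
#' independently of the locus. Planted-SNP genotypes are drawn per site
#' at a site-specific alt frequency (uniform on [0.1, 0.9]) under
#' inbreeding coefficient F, independent of phenotype.
#'
#' @param spec A [CohortSpec-class].
#' @param truth A [LocusTruth-class].
#' @return A [Cohort-class].
#' @export
simulateCohort <- function(spec, truth) {
    stopifnot(is(spec, "CohortSpec"), is(truth, "LocusTruth"))
    validObject(spec)
    set.seed(stageSeed(spec@seed, "cohort"))
    n <- spec@nAccessions
    ids <- sprintf("acc%03d", seq_len(n))

    carrier <- runif(n) < spec@recombAlleleFreq
    allele <- ifelse(carrier, "recombinant", "ancestral")

    pColorless <- ifelse(carrier, spec@penetrance, spec@leak)
    colorless <- runif(n) < pColorless
    otherHilum <- setdiff(spec@categories$hilum, "colorless")
    hilum <- ifelse(colorless, "colorless",
                    sample(otherHilum, n, replace = TRUE))
    traits <- data.frame(
        accession_id = ids,
        seed_coat = sample(spec@categories$seed_coat, n, replace = TRUE),
        hilum = hilum,
        pubescence = sample(spec@categories$pubescence, n, replace = TRUE))

    sites <- snpSites(truth)
    gt <- matrix("0/0", nrow = nrow(sites), ncol = n,
                 dimnames = list(siteNames(sites), ids))
    if (nrow(sites)) {
        set.seed(stageSeed(spec@seed, "snp"))
        f <- spec@inbreeding
        for (s in seq_len(nrow(sites))) {
            p <- runif(1, 0.1, 0.9)
            probs <- c(`0/0` = (1 - p)^2 + f * p * (1 - p),
                       `0/1` = 2 * p * (1 - p) * (1 - f),
                       `1/1` = p^2 + f * p * (1 - p))
            gt[s, ] <- sample(names(probs), n, replace = TRUE, prob = probs)
        }
    }
    new("Cohort", sampleIds = ids, alleles = allele, traits = traits,
        snpGenotypes = gt)
}

siteNames <- function(sites) {
    sprintf("ancestral:%d:%s>%s", sites$pos + 1L, sites$ref, sites$alt)
}
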