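#' Write sequences as FASTA
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFastaFile <- function(seqs, path) {
    if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path, format = "fasta")
    invisible(path)
}

#' Write reads as FASTQ with constant placeholder qualities
#'
#' Phred qualities are the constant "I"; nothing in the pipeline uses
#' qualities.
#'
#' @param reads Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path (gzip if it ends in .gz).
#' @return Invisibly, the path.
#' @export
writeFastqFile <- function(reads, path) {
    if (!is(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
    if (is.null(names(reads)))
        names(reads) <- paste0("read", seq_along(reads))
    quals <- Biostrings::BStringSet(
        vapply(Biostrings::width(reads),
               function(w) strrep("I", w), character(1)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals,
                                compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Write the locus gene models as GFF3
#'
#' Gene and exon features, 1-based coordinates, exon Parent
#' attributes; emitted through `rtracklayer`.
#'
#' @param truth A [LocusTruth-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeGff3File <- function(truth, path) {
    gm <- geneModels(truth)
    rows <- list()
    for (g in unique(gm$gene_id)) {
        e <- gm[gm$gene_id == g, ]
        rows[[length(rows) + 1L]] <- data.frame(
            seqnames = e$contig[1], start = min(e$start) + 1L,
            end = max(e$end), strand = e$strand[1], type = "gene",
            ID = g, Parent = NA_character_)
        rows[[length(rows) + 1L]] <- data.frame(
            seqnames = e$contig, start = e$start + 1L, end = e$end,
            strand = e$strand, type = "exon",
            ID = sprintf("%s.exon%d", g, seq_len(nrow(e))), Parent = g)
    }
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
        seqnames = df$seqnames,
        ranges = IRanges::IRanges(start = df$start, end = df$end),
        strand = df$strand, type = df$type, ID = df$ID)
    gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Builds [GeneModel-class] objects from exon features grouped by
#' their Parent attribute.
#'
#' @param path GFF3 path.
#' @param contig Optional contig filter.
#' @return Named list of [GeneModel-class].
#' @export
readGeneModels <- function(path, contig = NULL) {
    gr <- rtracklayer::import(path, format = "gff3")
    ex <- gr[gr$type == "exon"]
    parent <- as.character(ex$Parent)
    out <- list()
    for (g in unique(parent)) {
        e <- ex[parent == g]
        if (!is.null(contig) &&
            !as.character(GenomicRanges::seqnames(e))[1] %in% contig)
            next
        o <- order(GenomicRanges::start(e))
        out[[g]] <- geneModel(
            g, as.character(GenomicRanges::seqnames(e))[1],
            as.character(GenomicRanges::strand(e))[1],
            GenomicRanges::start(e)[o] - 1L, GenomicRanges::end(e)[o])
    }
    out
}

#' Write the planted-SNP truth VCF for a cohort
#'
#' Biallelic records on the ancestral contig with per-sample GT
#' calls — the reference-based call set the k-mer-derived genotypes
#' are scored against.
#'
#' @param truth A [LocusTruth-class].
#' @param cohort A [Cohort-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTruthVcfFile <- function(truth, cohort, path) {
    sites <- snpSites(truth)
    gt <- snpGenotypes(cohort)
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=ancestral,length=%d>",
                     nchar(ancestralSeq(truth))),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", sampleIds(cohort)),
                   collapse = "\t"))
    body <- paste("ancestral", sites$pos + 1L, siteNames(sites),
                  sites$ref, sites$alt, ".", ".", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Write the cohort phenotype table
#'
#' TSV with columns accession_id, seed_coat, hilum, pubescence.
#'
#' @param cohort A [Cohort-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writePhenotypeTable <- function(cohort, path) {
    write.table(traitTable(cohort), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write the truth allele table
#'
#' TSV with columns accession_id, allele.
#'
#' @param cohort A [Cohort-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeAlleleTable <- function(cohort, path) {
    write.table(data.frame(accession_id = sampleIds(cohort),
                           allele = alleles(cohort)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Simulate a full synthetic study into a directory
#'
#' Writes the reference FASTA (ancestral and recombinant haplotypes),
#' gene models (GFF3), truth VCF of planted SNPs, phenotype and
#' truth-allele tables, per-accession WGR FASTQ, the chimeric-gene
#' mRNA FASTQ and the small-RNA FASTQ.
#'
#' @param blueprint A [LocusBlueprint-class].
#' @param spec A [CohortSpec-class].
#' @param params A [ReadSimParams-class] for WGR reads.
#' @param outDir Output directory (created if needed).
#' @param mrnaDepth Fold coverage of the chimeric transcript.
#' @param nSmallRna Small-RNA reads per class (primary/secondary).
#' @param gzipFastq Compress FASTQ output.
#' @return Invisibly, a list with the truth and cohort objects and
#'   the written paths.
#' @export
simulateToDir <- function(blueprint, spec, params, outDir,
                          mrnaDepth = 50, nSmallRna = 2000L,
                          gzipFastq = FALSE) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    truth <- buildLocusPair(blueprint)
    cohort <- simulateCohort(spec, truth)
    ext <- if (gzipFastq) ".fq.gz" else ".fq"
    writeFastaFile(c(ancestral = ancestralSeq(truth),
                     recombinant = recombinantSeq(truth)),
                   file.path(outDir, "reference.fa"))
    writeGff3File(truth, file.path(outDir, "genes.gff3"))
    writeTruthVcfFile(truth, cohort, file.path(outDir, "truth.vcf"))
    writePhenotypeTable(cohort, file.path(outDir, "phenotypes.tsv"))
    writeAlleleTable(cohort, file.path(outDir, "alleles.tsv"))
    wgrDir <- file.path(outDir, "wgr")
    dir.create(wgrDir, showWarnings = FALSE)
    ids <- sampleIds(cohort)
    gts <- snpGenotypes(cohort)
    for (i in seq_along(ids)) {
        haps <- sampleHaplotypes(truth, alleles(cohort)[i], gts[, i])
        p <- new("ReadSimParams", readLen = params@readLen,
                 depth = params@depth, err = params@err,
                 paired = params@paired,
                 seed = as.integer((params@seed + 13L * i) %% 2147483647))
        writeFastqFile(simulateWgrReads(haps, p),
                       file.path(wgrDir, paste0(ids[i], ext)))
    }
    mrna <- simulateMrnaReads(truth, readSimParams(
        readLen = params@readLen, depth = mrnaDepth, err = params@err,
        seed = params@seed))
    writeFastqFile(mrna, file.path(outDir, paste0("mrna", ext)))
    srna <- simulateSmallRnaReads(truth, nPrimary = nSmallRna,
                                  nSecondary = nSmallRna,
                                  seed = params@seed)
    writeFastqFile(srna, file.path(outDir, paste0("srna", ext)))
    invisible(list(truth = truth, cohort = cohort, dir = outDir))
}
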