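# Shared in-code fixtures. Heavier simulated bundles are built once per
# test run and memoized here.

.fixtureEnv <- new.env(parent = emptyenv())

cachedFixture <- function(profile, seed = 7) {
    key <- paste0(profile, "_", seed)
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- makeFixture(profile, dir = NULL, seed = seed)
    .fixtureEnv[[key]]
}

# A small hand-built VariantTable: `n` SNVs on chr1/chr2 (10 Mb each),
# `samples` columns, deterministic under seed.
toyTable <- function(n = 200, samples = c("s1", "s2", "s3"), seed = 1,
                     qual = NULL) {
    set.seed(seed)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    pos <- sample.int(1e7, n)
    geno <- matrix(sample(c(0L, 1L, 2L, NA), n * length(samples),
                          replace = TRUE, prob = c(.4, .3, .25, .05)),
                   n, dimnames = list(NULL, samples))
    depth <- matrix(rpois(n * length(samples), 20), n,
                    dimnames = list(NULL, samples))
    mu <- matrix(0.02, n, length(samples))
    mu[!is.na(geno) & geno == 1L] <- 0.5
    mu[!is.na(geno) & geno == 2L] <- 0.98
    alt <- matrix(rbinom(n * length(samples), as.vector(depth),
                         as.vector(mu)), n,
                  dimnames = list(NULL, samples))
    if (is.null(qual)) qual <- round(runif(n, 10, 100), 1)
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(pos, width = 1L),
        seqinfo = genomeBuild(c("chr1", "chr2"), c(1e7, 1e7)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = rep("A", n), alt = rep("G", n), qual = qual,
        indel = rep(FALSE, n))
    manifest <- data.frame(sample = samples, class = "affected",
                           pedigree = "p1")
    ord <- order(as.integer(factor(chrom, c("chr1", "chr2"))), pos)
    VariantTable(gr[ord], geno[ord, , drop = FALSE],
                 depth[ord, , drop = FALSE], alt[ord, , drop = FALSE],
                 manifest)
}

# Build a VariantTable from explicit matrices at given positions.
tableAt <- function(chrom, pos, geno, depth, alt, qual = 50,
                    genome = genomeBuild(c("chr1", "chr2"), c(1e7, 1e7)),
                    classes = NULL) {
    samples <- colnames(geno)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                                 seqinfo = genome)
    n <- length(gr)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = rep("A", n), alt = rep("G", n),
        qual = rep_len(qual, n), indel = rep(FALSE, n))
    manifest <- data.frame(
        sample = samples,
        class = if (is.null(classes)) rep("affected", length(samples))
                else classes,
        pedigree = "p1")
    VariantTable(gr, geno, depth, alt, manifest)
}

# Minimal VCF text for reader tests.
vcfHeader <- function(samples, contigs = c(chr1 = 1e7)) {
    c("##fileformat=VCFv4.2",
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs)),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samples), collapse = "\t"))
}

writeTempVcf <- function(lines, ext = ".vcf") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}

manifestFor <- function(samples, class = "affected", pedigree = "p1") {
    data.frame(sample = samples, class = class, pedigree = pedigree,
               stringsAsFactors = FALSE)
}
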