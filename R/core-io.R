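#' @importFrom VariantAnnotation readVcf geno alt ref qual
#' @importFrom utils read.delim write.table
NULL

#' Construct a genome build
#'
#' Thin wrapper around [GenomeInfoDb::Seqinfo] holding the ordered chromosome
#' extents that windows are tiled over.
#'
#' @param chroms character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths (bp), all positive.
#' @return a `Seqinfo` object.
#' @examples
#' genomeBuild(c("chr1", "chr2"), c(10e6, 8e6))
#' @export
genomeBuild <- function(chroms, lengths) {
    if (anyDuplicated(chroms)) stop("chromosome names must be unique")
    if (any(lengths <= 0)) stop("chromosome lengths must be positive")
    Seqinfo(seqnames = as.character(chroms),
            seqlengths = as.integer(lengths))
}

#' Read a sample manifest
#'
#' Tab-separated file with header `sample  class  pedigree` assigning each
#' sequenced sample to a phenotype class and pedigree/founder.
#'
#' @param path path to the TSV manifest.
#' @return `data.frame` with columns `sample`, `class`, `pedigree`.
#' @export
readSampleManifest <- function(path) {
    m <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "class", "pedigree")
    if (!all(need %in% names(m)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(m$sample))
        stop("duplicate sample ids in manifest: ",
             paste(unique(m$sample[duplicated(m$sample)]), collapse = ", "))
    m[need]
}

#' Build a VariantTable from its parts
#'
#' @param gr `GRanges` of variant positions (width-1 anchors at POS) with
#'   metadata columns `ref`, `alt`, `qual`, `indel`.
#' @param geno,depth,altReads matrices (variants x samples); `geno` holds alt
#'   dosages 0/1/2/NA.
#' @param manifest `data.frame` with `sample`, `class`, `pedigree` covering
#'   every column of the matrices.
#' @return a [VariantTable].
#' @export
VariantTable <- function(gr, geno, depth, altReads, manifest) {
    samples <- colnames(geno)
    if (is.null(samples)) stop("genotype matrix needs sample column names")
    miss <- setdiff(samples, manifest$sample)
    if (length(miss))
        stop("samples absent from manifest: ", paste(miss, collapse = ", "))
    cd <- DataFrame(manifest[match(samples, manifest$sample), , drop = FALSE])
    rownames(cd) <- samples
    se <- SummarizedExperiment(
        assays = list(geno = geno, depth = depth, altReads = altReads),
        rowRanges = gr, colData = cd[, c("class", "pedigree"), drop = FALSE])
    new("VariantTable", se)
}

.parseDosage <- function(gt, altIndex) {
    # dosage of this row's alt allele within a possibly multiallelic GT
    out <- integer(length(gt))
    alleles <- strsplit(gt, "[/|]")
    for (i in seq_along(alleles)) {
        a <- alleles[[i]]
        if (any(a == ".") || !length(a)) out[i] <- NA_integer_
        else out[i] <- sum(a == as.character(altIndex[i]))
    }
    out
}

.checkVcfShape <- function(path) {
    lines <- readLines(path)
    body <- which(!startsWith(lines, "#"))
    hdr <- grep("^#CHROM", lines)
    if (!length(hdr)) stop("malformed VCF (no #CHROM header line): ", path)
    nfield <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
    for (i in body) {
        n <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
        if (n != nfield)
            stop("malformed VCF at line ", i, ": expected ", nfield,
                 " fields, found ", n)
    }
    invisible(TRUE)
}

#' Read a multi-sample VCF into a VariantTable
#'
#' Each biallelic row becomes one record; multiallelic rows are split into one
#' record per alternate allele (genotype dosage, depth and allelic depth are
#' re-expressed relative to that allele). Indel records are flagged via the
#' `indel` metadata column but retained.
#'
#' @param path VCF 4.x file with per-sample `GT`, `DP` and `AD` fields.
#' @param manifest manifest `data.frame` (see [readSampleManifest]); every
#'   manifest sample must be present in the VCF and vice versa.
#' @param validate pre-scan the file for ragged rows so parse errors report a
#'   line number (default `TRUE`).
#' @return a [VariantTable].
#' @export
readVariants <- function(path, manifest, validate = TRUE) {
    if (validate) .checkVcfShape(path)
    v <- suppressWarnings(VariantAnnotation::readVcf(path))
    vcfSamples <- rownames(colData(v))
    miss <- setdiff(manifest$sample, vcfSamples)
    if (length(miss))
        stop("manifest sample(s) missing from VCF: ",
             paste(miss, collapse = ", "))
    extra <- setdiff(vcfSamples, manifest$sample)
    if (length(extra))
        stop("VCF sample(s) absent from manifest: ",
             paste(extra, collapse = ", "))
    if (nrow(v) == 0L) {
        gr <- GRanges(seqinfo = GenomeInfoDb::seqinfo(v))
        mcols(gr) <- DataFrame(ref = character(), alt = character(),
                               qual = numeric(), indel = logical())
        m0 <- matrix(integer(), 0L, length(vcfSamples),
                     dimnames = list(NULL, vcfSamples))
        return(VariantTable(gr, m0, m0, m0, manifest))
    }
    nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(v))
    ve <- VariantAnnotation::expand(v)
    altIdx <- unlist(lapply(nAlt, seq_len), use.names = FALSE)
    if (!length(altIdx)) altIdx <- integer(0)

    gt <- VariantAnnotation::geno(ve)$GT
    dp <- VariantAnnotation::geno(ve)$DP
    ad <- VariantAnnotation::geno(ve)$AD
    samples <- vcfSamples
    n <- nrow(ve)
    geno <- matrix(NA_integer_, n, length(samples),
                   dimnames = list(NULL, samples))
    for (j in seq_along(samples))
        geno[, j] <- .parseDosage(gt[, j], altIdx)
    depth <- matrix(as.integer(dp), n, length(samples),
                    dimnames = list(NULL, samples))
    altmat <- if (length(dim(ad)) == 3L) {
        m <- ad[, , 2L, drop = FALSE]; dim(m) <- dim(ad)[1:2]
        colnames(m) <- samples
        matrix(as.integer(m), n, length(samples),
               dimnames = list(NULL, samples))
    } else matrix(NA_integer_, n, length(samples),
                  dimnames = list(NULL, samples))
    depth[is.na(depth)] <- 0L
    altmat[is.na(altmat)] <- 0L
    geno[depth == 0L] <- NA_integer_

    rr <- rowRanges(ve)
    refs <- as.character(VariantAnnotation::ref(ve))
    alts <- as.character(VariantAnnotation::alt(ve))
    gr <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L),
                  seqinfo = GenomeInfoDb::seqinfo(ve))
    mcols(gr) <- DataFrame(ref = refs, alt = alts,
                           qual = as.numeric(VariantAnnotation::qual(ve)),
                           indel = nchar(refs) != 1L | nchar(alts) != 1L)
    names(gr) <- NULL
    VariantTable(gr, geno, depth, altmat, manifest)
}

#' Write a VariantTable to VCF 4.2
#'
#' Emits one row per record with `GT:DP:AD` sample fields; re-reading with
#' [readVariants] reproduces genotypes, depths and alt read counts exactly.
#'
#' @param x a [VariantTable].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(x, path) {
    gr <- rowRanges(x)
    geno <- genotypes(x); dp <- depths(x); ad <- altReads(x)
    gtStr <- matrix("./.", nrow(x), ncol(x))
    gtStr[!is.na(geno) & geno == 0L] <- "0/0"
    gtStr[!is.na(geno) & geno == 1L] <- "0/1"
    gtStr[!is.na(geno) & geno == 2L] <- "1/1"
    fields <- matrix(paste0(gtStr, ":", dp, ":", dp - ad, ",", ad),
                     nrow(x), ncol(x))
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>",
                     seqlevels(gr), seqlengths(gr)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(x)), collapse = "\t"))
    qualStr <- ifelse(is.na(mcols(gr)$qual), ".",
                      sub("\\.0+$", "", format(mcols(gr)$qual,
                                               scientific = FALSE, trim = TRUE)))
    body <- if (nrow(x)) paste(
        as.character(seqnames(gr)), start(gr), ".", mcols(gr)$ref,
        mcols(gr)$alt, qualStr, ".", ".", "GT:DP:AD",
        apply(fields, 1L, paste, collapse = "\t"), sep = "\t") else character()
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read exclusion sets
#'
#' Each category is a BED file (positional intervals, 0-based half-open on
#' disk, converted at this boundary) or a VCF of known sites (matched on
#' chromosome, position and -- when allele-aware -- alternate allele).
#' Overlapping intervals are merged.
#'
#' @param paths named list/vector of file paths; names are category labels
#'   (e.g. `dbsnp`, `strain`, `pedigree`, `repeats`).
#' @param alleleAware named logical, per *site* category; defaults to `TRUE`
#'   for every site category. Interval categories are always positional.
#' @return an [ExclusionSet].
#' @export
readExclusions <- function(paths, alleleAware = NULL) {
    if (is.null(names(paths)) || any(names(paths) == ""))
        stop("every exclusion path must be named by its category")
    intervals <- list(); sites <- list()
    for (cat in names(paths)) {
        p <- paths[[cat]]
        if (grepl("\\.bed(\\.gz)?$", p, ignore.case = TRUE)) {
            gr <- rtracklayer::import(p, format = "BED")
            intervals[[cat]] <- reduce(granges(gr))
        } else if (grepl("\\.vcf(\\.gz)?$", p, ignore.case = TRUE)) {
            v <- VariantAnnotation::expand(
                suppressWarnings(VariantAnnotation::readVcf(p)))
            g <- GRanges(seqnames(rowRanges(v)),
                         IRanges(start(rowRanges(v)), width = 1L))
            mcols(g)$alt <- as.character(VariantAnnotation::alt(v))
            names(g) <- NULL
            sites[[cat]] <- unique(g)
        } else stop("unknown exclusion file extension for category '", cat,
                    "': ", p)
    }
    aa <- rep(TRUE, length(sites)); names(aa) <- names(sites)
    if (!is.null(alleleAware)) {
        bad <- setdiff(names(alleleAware), names(sites))
        if (length(bad))
            stop("alleleAware names not site categories: ",
                 paste(bad, collapse = ", "))
        aa[names(alleleAware)] <- alleleAware
    }
    new("ExclusionSet",
        intervals = GRangesList(intervals, compress = FALSE),
        sites = GRangesList(sites, compress = FALSE), alleleAware = aa)
}

#' Construct an ExclusionSet from in-memory ranges
#'
#' @param intervals named list of `GRanges` (positional categories).
#' @param sites named list of `GRanges` with an `alt` metadata column.
#' @param alleleAware named logical per site category (default all `TRUE`).
#' @return an [ExclusionSet].
#' @export
ExclusionSet <- function(intervals = list(), sites = list(),
                         alleleAware = NULL) {
    intervals <- lapply(intervals, function(g) reduce(granges(g)))
    aa <- rep(TRUE, length(sites)); names(aa) <- names(sites)
    if (!is.null(alleleAware)) aa[names(alleleAware)] <- alleleAware
    new("ExclusionSet",
        intervals = GRangesList(intervals, compress = FALSE),
        sites = GRangesList(sites, compress = FALSE), alleleAware = aa)
}

#' Which exclusion categories hit each variant
#'
#' @param excl an [ExclusionSet].
#' @param x a [VariantTable] or `GRanges` with an `alt` metadata column.
#' @param categories categories to test (default: all).
#' @return logical matrix, variants x categories.
#' @export
exclusionHits <- function(excl, x, categories = NULL) {
    gr <- if (is(x, "VariantTable")) rowRanges(x) else x
    cats <- c(names(excl@intervals), names(excl@sites))
    if (!is.null(categories)) {
        bad <- setdiff(categories, cats)
        if (length(bad)) stop("unknown categories: ",
                              paste(bad, collapse = ", "))
        cats <- intersect(cats, categories)
    }
    out <- matrix(FALSE, length(gr), length(cats),
                  dimnames = list(NULL, cats))
    for (cat in cats) {
        if (cat %in% names(excl@intervals)) {
            out[, cat] <- suppressWarnings(
                overlapsAny(gr, excl@intervals[[cat]],
                            ignore.strand = TRUE))
        } else {
            s <- excl@sites[[cat]]
            if (excl@alleleAware[[cat]]) {
                key <- paste(as.character(seqnames(gr)), start(gr),
                             mcols(gr)$alt)
                skey <- paste(as.character(seqnames(s)), start(s),
                              mcols(s)$alt)
            } else {
                key <- paste(as.character(seqnames(gr)), start(gr))
                skey <- paste(as.character(seqnames(s)), start(s))
            }
            out[, cat] <- key %in% skey
        }
    }
    out
}

#' Read exon/CDS gene models from GFF3 or GTF
#'
#' Only `exon` and `CDS` features are kept; a feature without a parent or
#' gene attribution is skipped with a warning.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @return a [GeneModel].
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path)
    .pick <- function(g) {
        gene <- if (!is.null(g$gene_id)) as.character(g$gene_id)
                else rep(NA_character_, length(g))
        parent <- if (!is.null(g$Parent))
            vapply(as.list(g$Parent), function(p)
                if (length(p)) as.character(p[1]) else NA_character_,
                character(1))
            else if (!is.null(g$transcript_id)) as.character(g$transcript_id)
            else rep(NA_character_, length(g))
        gene[is.na(gene)] <- parent[is.na(gene)]
        orphan <- is.na(gene)
        if (any(orphan))
            warning(sum(orphan), " feature(s) without parent/gene skipped")
        g <- g[!orphan]
        mcols(g) <- DataFrame(gene = gene[!orphan],
                              transcript = parent[!orphan])
        g
    }
    exons <- .pick(gr[tolower(as.character(gr$type)) == "exon"])
    cds <- .pick(gr[toupper(as.character(gr$type)) == "CDS"])
    new("GeneModel", exons = granges(exons, use.mcols = TRUE),
        cds = granges(cds, use.mcols = TRUE))
}

#' Construct a GeneModel from ranges
#'
#' @param exons,cds `GRanges` with `gene` (and optionally `transcript`)
#'   metadata columns.
#' @return a [GeneModel].
#' @export
GeneModel <- function(exons, cds = GRanges()) {
    .fill <- function(g) {
        if (length(g) && is.null(mcols(g)$gene)) mcols(g)$gene <- NA_character_
        if (length(g) && is.null(mcols(g)$transcript))
            mcols(g)$transcript <- mcols(g)$gene
        g
    }
    new("GeneModel", exons = .fill(exons), cds = .fill(cds))
}
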