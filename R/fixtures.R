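#' @importFrom jsonlite write_json
NULL

.writeSitesVcf <- function(gr, path) {
    hdr <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"))
    body <- if (length(gr)) paste(
        as.character(seqnames(gr)), start(gr), ".",
        if (!is.null(mcols(gr)$ref)) mcols(gr)$ref else "N",
        mcols(gr)$alt, ".", ".", ".", sep = "\t") else character()
    writeLines(c(hdr, body), path)
    invisible(path)
}

.writeBed <- function(gr, path) {
    df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write a GeneModel as GFF3
#'
#' @param genes a [GeneModel].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModelGff <- function(genes, path) {
    .feat <- function(gr, type) {
        if (!length(gr)) return(character())
        sprintf("%s\tenuscan\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;gene_id=%s",
                as.character(seqnames(gr)), type, start(gr), end(gr),
                ifelse(as.character(strand(gr)) == "*", "+",
                       as.character(strand(gr))),
                paste0(type, ":", mcols(gr)$transcript, ":", seq_along(gr)),
                mcols(gr)$transcript, mcols(gr)$gene)
    }
    ex <- exonRanges(genes)
    tx <- unique(data.frame(chrom = as.character(seqnames(ex)),
                            tx = mcols(ex)$transcript,
                            gene = mcols(ex)$gene))
    rng <- vapply(tx$tx, function(t) {
        e <- ex[mcols(ex)$transcript == t]
        c(min(start(e)), max(end(e)))
    }, integer(2))
    mrna <- sprintf("%s\tenuscan\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;gene_id=%s",
                    tx$chrom, rng[1, ], rng[2, ], tx$tx, tx$gene)
    writeLines(c("##gff-version 3", mrna, .feat(ex, "exon"),
                 .feat(cdsRanges(genes), "CDS")), path)
    invisible(path)
}

#' Write alignments in the TSV dialect
#'
#' @param aln alignment `data.frame` (`sample`, `chrom`, `pos`, `cigar`,
#'   optional `remap`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAlignmentsTsv <- function(aln, path) {
    write.table(aln, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.cigarReadLen <- function(cigar) {
    co <- .cigarOps(cigar)
    sum(co$lens[co$ops %in% c("M", "I", "S", "=", "X")])
}

#' Write alignments as SAM
#'
#' Minimal single-end SAM with sequences of Ns, for exercising the
#' CIGAR-based soft-clip scanner through the standard alignment format.
#'
#' @param aln alignment `data.frame` as in [writeAlignmentsTsv].
#' @param genome `Seqinfo` for the `@SQ` header lines.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAlignmentsSam <- function(aln, genome, path) {
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", seqlevels(genome),
                     seqlengths(genome)))
    ord <- order(aln$chrom, aln$pos)
    aln <- aln[ord, , drop = FALSE]
    body <- vapply(seq_len(nrow(aln)), function(i) {
        len <- .cigarReadLen(aln$cigar[i])
        paste(sprintf("read%06d_%s", i, aln$sample[i]), 0, aln$chrom[i],
              aln$pos[i], 60, aln$cigar[i], "*", 0, 0,
              strrep("N", len), "*", paste0("RG:Z:", aln$sample[i]),
              sep = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
    invisible(path)
}

.mergeExclusionSets <- function(a, b) {
    cats <- union(names(a@sites), names(b@sites))
    sites <- lapply(cats, function(cc) {
        g <- GRangesList(c(if (cc %in% names(a@sites)) list(a@sites[[cc]]),
                           if (cc %in% names(b@sites)) list(b@sites[[cc]])))
        unique(unlist(g))
    })
    names(sites) <- cats
    icats <- union(names(a@intervals), names(b@intervals))
    ints <- lapply(icats, function(cc) {
        g <- GRangesList(c(if (cc %in% names(a@intervals))
                               list(a@intervals[[cc]]),
                           if (cc %in% names(b@intervals))
                               list(b@intervals[[cc]])))
        reduce(unlist(g))
    })
    names(ints) <- icats
    ExclusionSet(intervals = ints, sites = sites)
}

.fixtureSeeds <- function(seed) {
    # derived sub-seeds, kept well below 2^31
    c(a = (seed * 1000L + 11L) %% 1000000L,
      b = (seed * 1000L + 77L) %% 1000000L)
}

#' Build a named reproducible fixture bundle
#'
#' Profiles:
#' \describe{
#'   \item{`fosse_like`}{two pedigrees sequenced as one eight-sample cohort
#'     (6 + 2) with distinct causal loci on chr1 and chr4 -- exercises
#'     cohort partitioning.}
#'   \item{`timon_like`}{three affected samples on a chr7+chr18 genome; a
#'     recombination tight around the causal locus limits the shared
#'     homozygous interval to ~0.5 Mb, and a 1696 bp deletion
#'     (chr18:58,012,626-58,014,322, half-open) is planted with
#'     soft-clipped read support -- exercises window refinement and the
#'     split-read scanner.}
#'   \item{`modifier_like`}{one pedigree, eight affected embryos split 5/3
#'     into cleft-palate-like and exencephaly-like classes by carriage of a
#'     planted dominant modifier -- exercises the modifier screen.}
#' }
#'
#' With `dir = NULL` nothing is written and the in-memory objects are
#' returned. Otherwise the bundle (VCF, manifest TSV, exclusion VCF/BED,
#' GFF3, alignment TSV + SAM where applicable, truth JSON) is written under
#' `dir`; identical `profile` + `seed` regenerate identical files.
#'
#' @param profile one of `"fosse_like"`, `"timon_like"`,
#'   `"modifier_like"`.
#' @param dir output directory, or `NULL` for in-memory only.
#' @param seed integer seed.
#' @return list with elements among `variants` ([VariantTable]),
#'   `exclusions`, `genes`, `alignments`, `truth`, `screens`, `paths`.
#' @export
makeFixture <- function(profile = c("fosse_like", "timon_like",
                                    "modifier_like"),
                        dir = NULL, seed = 1) {
    profile <- match.arg(profile)
    seeds <- .fixtureSeeds(as.integer(seed))
    if (profile == "fosse_like") {
        cfgA <- simConfig(causalChrom = "chr1", causalPos = 1.5e7,
                          nAffected = 6, seed = seeds[["a"]])
        cfgB <- simConfig(causalChrom = "chr4", causalPos = 1.5e7,
                          nAffected = 2, seed = seeds[["b"]])
        scrA <- simulateScreen(cfgA, samplePrefix = "mutA")
        scrB <- simulateScreen(cfgB, samplePrefix = "mutB")
        vt <- mergeScreens(scrA, scrB)
        out <- list(variants = vt,
                    exclusions = .mergeExclusionSets(scrA@exclusions,
                                                     scrB@exclusions),
                    genes = scrA@genes,
                    truth = list(
                        profile = profile,
                        groups = list(
                            list(samples = colnames(scrA@variants),
                                 causal_chrom = "chr1", causal_pos = 1.5e7),
                            list(samples = colnames(scrB@variants),
                                 causal_chrom = "chr4", causal_pos = 1.5e7))),
                    screens = list(a = scrA, b = scrB))
    } else if (profile == "timon_like") {
        cfg <- simConfig(
            genome = genomeBuild(c("chr7", "chr18"), c(4e7, 6e7)),
            causalChrom = "chr18", causalPos = 58050000,
            deletion = list(chrom = "chr18", start = 58012626L,
                            end = 58014322L),
            nAffected = 3, seed = seeds[["a"]])
        scr <- simulateScreen(cfg, samplePrefix = "tim",
                              forcedRecomb = list(sample = 3,
                                                  halfWidth = 250000L))
        out <- list(variants = scr@variants, exclusions = scr@exclusions,
                    genes = scr@genes, alignments = scr@alignments,
                    truth = c(scr@truth,
                              list(profile = profile,
                                   hom_interval = list(
                                       chrom = "chr18",
                                       start = 58050000 - 250000,
                                       end = 58050000 + 250000),
                                   search_region = list(
                                       chrom = "chr18", start = 54000000,
                                       end = 60000000))),
                    screens = list(scr))
    } else {
        cfg <- simConfig(modifier = list(chrom = "chr5", pos = 1.5e7),
                         seed = seeds[["a"]])
        scr <- simulateScreen(cfg, samplePrefix = "fos",
                              classes = c(cleft_palate = 5L,
                                          exencephaly = 3L))
        out <- list(variants = scr@variants, exclusions = scr@exclusions,
                    genes = scr@genes,
                    truth = c(scr@truth, list(profile = profile)),
                    screens = list(scr))
    }
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        p <- list(vcf = file.path(dir, "variants.vcf"),
                  manifest = file.path(dir, "manifest.tsv"),
                  gff = file.path(dir, "genes.gff3"),
                  truth = file.path(dir, "truth.json"))
        writeVariants(out$variants, p$vcf)
        mf <- data.frame(sample = colnames(out$variants),
                         class = colData(out$variants)$class,
                         pedigree = colData(out$variants)$pedigree)
        write.table(mf, p$manifest, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        writeGeneModelGff(out$genes, p$gff)
        excl <- out$exclusions
        for (cat in names(excl@sites)) {
            p[[cat]] <- file.path(dir, paste0(cat, ".vcf"))
            .writeSitesVcf(excl@sites[[cat]], p[[cat]])
        }
        for (cat in names(excl@intervals)) {
            p[[cat]] <- file.path(dir, paste0(cat, ".bed"))
            .writeBed(excl@intervals[[cat]], p[[cat]])
        }
        if (!is.null(out$alignments) && nrow(out$alignments)) {
            p$alignments <- file.path(dir, "alignments.tsv")
            writeAlignmentsTsv(out$alignments, p$alignments)
            p$sam <- file.path(dir, "alignments.sam")
            writeAlignmentsSam(out$alignments,
                               out$screens[[1]]@config@genome, p$sam)
        }
        write_json(out$truth, p$truth, auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
        out$paths <- p
    }
    out
}
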